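#' Define a residue region
#'
#' A named set of residues (e.g. the S4 or S6 helix, or the selectivity
#' filter) used as source/target for minimal-path queries. Membership is
#' user-supplied configuration: the helix/filter boundaries of a real
#' channel come from its structure annotation.
#'
#' @param name Region label, e.g. `"S4"`.
#' @param members Character vector of residue keys (`"chain:resno"`), or
#'   a tibble with `chain` and `resno` columns.
#' @return A `residue_region` object.
#' @export
residue_region <- function(name, members) {
  if (is.data.frame(members)) members <- residue_keys(members)
  members <- unique(as.character(members))
  if (length(members) == 0L) abort("A region must have at least one member.")
  structure(list(name = name, members = members), class = "residue_region")
}

as_region <- function(x, name = "region") {
  if (inherits(x, "residue_region")) x else residue_region(name, x)
}

#' Build the residue communication graph
#'
#' Nodes are all residues of the weight matrix; undirected edges carry
#' the finite `-log(C * M')` weights. Regions are validated against the
#' node set and stored on the graph.
#'
#' @param W A [build_weight_matrix()] result.
#' @param regions Named list of [residue_region()] objects (or plain key
#'   vectors, which are promoted using their list names).
#' @return A `coupling_graph` (igraph graph plus region map).
#' @export
build_graph <- function(W, regions = list()) {
  stopifnot(inherits(W, "weight_matrix"))
  keys <- rownames(W$W) %||% as.character(seq_len(nrow(W$W)))
  edges <- as_tibble(W)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = keys))
  if (length(regions)) {
    if (is.null(names(regions))) names(regions) <- vapply(regions, function(r) {
      if (inherits(r, "residue_region")) r$name else abort("Unnamed region list.")
    }, character(1))
    regions <- lapply(names(regions), function(nm) as_region(regions[[nm]], nm))
    names(regions) <- vapply(regions, `[[`, character(1), "name")
    for (r in regions) {
      missing <- setdiff(r$members, keys)
      if (length(missing)) {
        abort(sprintf("Region '%s' references residues absent from the graph: %s",
                      r$name, paste(missing, collapse = ", ")))
      }
    }
  }
  structure(list(graph = g, regions = regions), class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("<coupling_graph> %d residues, %d edges, %d region(s): %s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$regions), paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

new_allosteric_path <- function(nodes, length, source_region, target_region,
                                subunit = NA_character_, reachable = TRUE) {
  structure(
    list(nodes = nodes, length = length, source_region = source_region,
         target_region = target_region, subunit = subunit,
         reachable = reachable),
    class = "allosteric_path"
  )
}

#' @export
print.allosteric_path <- function(x, ...) {
  if (!x$reachable) {
    cat(sprintf("<allosteric_path> %s -> %s: unreachable\n",
                x$source_region, x$target_region))
  } else {
    cat(sprintf("<allosteric_path> %s -> %s: d_min = %.4f via %s\n",
                x$source_region, x$target_region, x$length,
                paste(x$nodes, collapse = " - ")))
  }
  invisible(x)
}

#' @method as_tibble allosteric_path
#' @export
as_tibble.allosteric_path <- function(x, ...) {
  tibble(source_region = x$source_region, target_region = x$target_region,
         subunit = x$subunit, reachable = x$reachable,
         d_min = if (x$reachable) x$length else NA_real_,
         n_nodes = length(x$nodes),
         path = paste(x$nodes, collapse = " - "))
}

# Deterministic choice among candidate paths of (numerically) equal
# length: fewest hops first, then lexicographically smallest node
# sequence.
pick_path <- function(paths) {
  hops <- lengths(paths)
  paths <- paths[hops == min(hops)]
  keysig <- vapply(paths, paste, character(1), collapse = "\r")
  paths[[order(keysig)[1]]]
}

path_weight <- function(g, nodes) {
  if (length(nodes) < 2L) return(0)
  eid <- igraph::get_edge_ids(g, rbind(nodes[-length(nodes)], nodes[-1]))
  sum(igraph::E(g)$weight[eid])
}

#' Minimal-weight path between two residue sets
#'
#' Dijkstra shortest path over all `(s, t)` pairs with `s` in
#' `source_set` and `t` in `target_set`; the region-to-region distance is
#' the minimum over member pairs. Ties are broken deterministically
#' (fewest hops, then lexicographic node order). If the sets intersect,
#' the shared node is a zero-length path. An unreachable pair yields a
#' typed unreachable result, not an error.
#'
#' @param graph A `coupling_graph` (or bare igraph with a `weight` edge
#'   attribute).
#' @param source_set,target_set Character vectors of residue keys, or
#'   [residue_region()] objects, or names of regions stored on the graph.
#' @return An `allosteric_path`.
#' @export
shortest_path <- function(graph, source_set, target_set) {
  g <- if (inherits(graph, "coupling_graph")) graph$graph else graph
  regions <- if (inherits(graph, "coupling_graph")) graph$regions else list()
  resolve <- function(x, default_name) {
    if (is.character(x) && length(x) == 1L && x %in% names(regions)) {
      return(regions[[x]])
    }
    as_region(x, default_name)
  }
  src <- resolve(source_set, "source")
  tgt <- resolve(target_set, "target")
  missing <- setdiff(c(src$members, tgt$members), igraph::V(g)$name)
  if (length(missing)) {
    abort(sprintf("Residues absent from the graph: %s",
                  paste(missing, collapse = ", ")))
  }

  shared <- intersect(src$members, tgt$members)
  if (length(shared)) {
    node <- sort(shared)[1]
    return(new_allosteric_path(node, 0, src$name, tgt$name))
  }

  dmat <- igraph::distances(g, v = src$members, to = tgt$members,
                            algorithm = "dijkstra")
  if (!any(is.finite(dmat))) {
    inform(sprintf("No path between regions '%s' and '%s'.", src$name, tgt$name))
    return(new_allosteric_path(character(0), NA_real_, src$name, tgt$name,
                               reachable = FALSE))
  }
  dmin <- min(dmat[is.finite(dmat)])
  hit <- which(dmat <= dmin + 1e-9, arr.ind = TRUE)
  cands <- list()
  for (k in seq_len(nrow(hit))) {
    s <- src$members[hit[k, 1]]
    t <- tgt$members[hit[k, 2]]
    asp <- igraph::all_shortest_paths(g, from = s, to = t)$res
    cands <- c(cands, lapply(asp, function(p) igraph::V(g)$name[p]))
  }
  best <- pick_path(cands)
  new_allosteric_path(best, path_weight(g, best), src$name, tgt$name)
}

# Split region members by chain (subunit) prefix of the residue key.
split_by_subunit <- function(region) {
  chains <- sub(":.*$", "", region$members)
  split(region$members, chains)
}

#' Per-subunit minimal path lengths between regions
#'
#' Computes `d_min` between a source and a target region, either per
#' subunit (chain) — pairing each chain's region members, the default for
#' a homotetramer — or globally over all members. `aggregate = "mean"`
#' replaces the min-over-member-pairs rule with the mean of all pairwise
#' shortest distances, as a sensitivity mode.
#'
#' @param graph A `coupling_graph`.
#' @param source_region,target_region Regions (see [shortest_path()]).
#' @param per_subunit Pair region members chain-by-chain (default TRUE).
#' @param aggregate `"min"` (region distance = best member pair, default)
#'   or `"mean"` (mean over member pairs).
#' @return A tibble with one row per subunit (or a single `"all"` row):
#'   `subunit`, `d_min`, `reachable`, `path`.
#' @export
minimal_path_length <- function(graph, source_region, target_region,
                                per_subunit = TRUE,
                                aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  g <- if (inherits(graph, "coupling_graph")) graph$graph else graph
  regions <- if (inherits(graph, "coupling_graph")) graph$regions else list()
  resolve <- function(x, nm) {
    if (is.character(x) && length(x) == 1L && x %in% names(regions)) regions[[x]]
    else as_region(x, nm)
  }
  src <- resolve(source_region, "source")
  tgt <- resolve(target_region, "target")

  pairs <- if (per_subunit) {
    s_sub <- split_by_subunit(src)
    t_sub <- split_by_subunit(tgt)
    shared_chains <- intersect(names(s_sub), names(t_sub))
    if (length(shared_chains) == 0L) {
      abort("No chain hosts members of both regions; use per_subunit = FALSE.")
    }
    lapply(shared_chains, function(ch) {
      list(subunit = ch,
           src = residue_region(src$name, s_sub[[ch]]),
           tgt = residue_region(tgt$name, t_sub[[ch]]))
    })
  } else {
    list(list(subunit = "all", src = src, tgt = tgt))
  }

  rows <- purrr::map_dfr(pairs, function(p) {
    if (aggregate == "mean") {
      dmat <- igraph::distances(g, v = p$src$members, to = p$tgt$members,
                                algorithm = "dijkstra")
      finite <- is.finite(dmat)
      if (!any(finite)) {
        warn(sprintf("Subunit %s: regions unreachable; excluded from averages.",
                     p$subunit))
        return(tibble(subunit = p$subunit, d_min = NA_real_,
                      reachable = FALSE, path = NA_character_))
      }
      if (!all(finite)) {
        warn(sprintf("Subunit %s: %d unreachable member pairs dropped from the mean.",
                     p$subunit, sum(!finite)))
      }
      return(tibble(subunit = p$subunit, d_min = mean(dmat[finite]),
                    reachable = TRUE, path = NA_character_))
    }
    path <- shortest_path(graph, p$src, p$tgt)
    if (!path$reachable) {
      warn(sprintf("Subunit %s: regions unreachable; excluded from averages.",
                   p$subunit))
    }
    tibble(subunit = p$subunit,
           d_min = if (path$reachable) path$length else NA_real_,
           reachable = path$reachable,
           path = if (path$reachable) paste(path$nodes, collapse = " - ")
                  else NA_character_)
  })
  rows
}

#' Residue betweenness centrality
#'
#' Shortest-path betweenness of every residue with edge weights as
#' distances (Brandes' algorithm, as implemented in igraph); endpoints
#' are excluded. Normalization divides by `(n-1)(n-2)/2`, the number of
#' node pairs that could route through a residue.
#'
#' @param graph A `coupling_graph` or igraph graph.
#' @param weighted Use edge weights as distances (default TRUE);
#'   otherwise hop counts.
#' @param normalized Also report betweenness scaled to `[0, 1]`.
#' @return A tibble `node`, `chain`, `resno`, `bc`, and `bc_norm` when
#'   `normalized`.
#' @export
betweenness_profile <- function(graph, weighted = TRUE, normalized = TRUE) {
  g <- if (inherits(graph, "coupling_graph")) graph$graph else graph
  w <- if (weighted) NULL else NA
  bc <- igraph::betweenness(g, directed = FALSE, weights = w)
  n <- igraph::vcount(g)
  out <- tibble(
    node = igraph::V(g)$name,
    chain = sub(":.*$", "", igraph::V(g)$name),
    resno = suppressWarnings(as.integer(sub("^.*:", "", igraph::V(g)$name))),
    bc = as.numeric(bc)
  )
  if (normalized) {
    denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    out$bc_norm <- out$bc / denom
  }
  out
}

#' Compare minimal paths between two graphs (mutant vs wild type)
#'
#' Computes the per-subunit `d_min` between the same two regions on a
#' wild-type and a mutant communication graph and summarizes the change
#' `delta = d_min(mut) - d_min(wt)` as mean and SD over subunits. A
#' positive delta means impaired communication in the mutant.
#'
#' @param wt,mut `coupling_graph` objects over the same residue universe
#'   (matched by residue key).
#' @param source_region,target_region Regions (see [shortest_path()]);
#'   region names must resolve on both graphs.
#' @param per_subunit Pair chains (default TRUE).
#' @return A `path_comparison`: tibble of per-subunit `d_min_wt`,
#'   `d_min_mut`, `delta`, with attributes `delta_mean` and `delta_sd`.
#' @export
compare_paths <- function(wt, mut, source_region, target_region,
                          per_subunit = TRUE) {
  stopifnot(inherits(wt, "coupling_graph"), inherits(mut, "coupling_graph"))
  a <- minimal_path_length(wt, source_region, target_region, per_subunit)
  b <- minimal_path_length(mut, source_region, target_region, per_subunit)
  if (!identical(a$subunit, b$subunit)) {
    abort("Region/subunit structure differs between the two graphs.")
  }
  out <- tibble(
    subunit = a$subunit,
    d_min_wt = a$d_min,
    d_min_mut = b$d_min,
    delta = b$d_min - a$d_min
  )
  ok <- !is.na(out$delta)
  attr(out, "delta_mean") <- mean(out$delta[ok])
  attr(out, "delta_sd") <- if (sum(ok) > 1) sd(out$delta[ok]) else NA_real_
  class(out) <- c("path_comparison", class(out))
  out
}

#' @export
print.path_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf("delta d_min = %.4f +/- %s (mean +/- SD over subunits)\n",
              attr(x, "delta_mean"),
              ifelse(is.na(attr(x, "delta_sd")), "NA",
                     sprintf("%.4f", attr(x, "delta_sd")))))
  invisible(x)
}

#' Correlate a network metric with energetic perturbations
#'
#' Pearson correlation and ordinary least-squares line between a
#' per-construct network metric (e.g. betweenness of the mutated residue,
#' or delta d_min) and the measured gating-energy perturbation.
#'
#' @param xs,ys Equal-length numeric vectors, `n >= 3`.
#' @return A one-row tibble: `r`, `slope`, `intercept`, `n`.
#' @export
correlate_metric_vs_energy <- function(xs, ys) {
  stopifnot(is.numeric(xs), is.numeric(ys))
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length.")
  ok <- complete.cases(xs, ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3L) abort("Need at least 3 complete pairs.")
  if (sd(xs) == 0 || sd(ys) == 0) {
    abort("Zero variance in `xs` or `ys`: correlation undefined.")
  }
  fit <- lm(ys ~ xs)
  tibble(r = cor(xs, ys),
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         n = length(xs))
}
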