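network_config_defaults <- list(
  topology = NULL, trajectory = NULL, selection = NULL,
  stride = 1L, first_frame = 1L, last_frame = NULL,
  superpose = TRUE, superpose_selection = NULL,
  c = 7.0, d_cut = 10.0, kernel_target = 1e-5,
  n_bins = 20L, log_base = "e", floor_eps = 1e-12,
  block_length = NULL, frame_time_ns = NULL,
  regions = list(), path_pairs = list(),
  seed = 1L, out_dir = NULL
)

energetics_config_defaults <- list(
  fits_csv = NULL, wt = "WT", faraday = FARADAY_KCAL,
  temperature = DEFAULT_TEMP_K,
  metrics_csv = NULL, metric_columns = NULL,
  out_dir = NULL, seed = 1L
)

#' Read and validate a run configuration
#'
#' Merges a YAML file (or a plain list) over the defaults of the chosen
#' pipeline stage. Unknown keys are rejected so typos fail before any
#' compute.
#'
#' @param config Path to a YAML file, or a named list.
#' @param kind `"network"` or `"energetics"`.
#' @return A validated config list.
#' @export
read_run_config <- function(config, kind = c("network", "energetics")) {
  kind <- match.arg(kind)
  defaults <- if (kind == "network") network_config_defaults
              else energetics_config_defaults
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, config)
}

checksum_or_na <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) return(list())
  files <- unlist(paths)
  sums <- tools::md5sum(files[file.exists(files)])
  as.list(sums)
}

write_manifest <- function(out_dir, config, outputs, timings, warnings) {
  manifest <- list(
    software = list(package = "gatingnet",
                    version = as.character(packageVersion("gatingnet")),
                    r_version = R.version.string),
    config = config,
    input_checksums = checksum_or_na(config[c("topology", "trajectory",
                                              "fits_csv", "metrics_csv")]),
    outputs = outputs,
    timings_s = timings,
    warnings = warnings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)  # atomic write at run end
  invisible(path)
}

#' Run the full network pipeline
#'
#' Load trajectory features, superpose, compute the contact map,
#' side-chain displacements and their normalized mutual information,
#' assemble the `-log(C * M')` weight matrix (with optional block-wise
#' uncertainties), extract region-to-region minimal paths and residue
#' betweenness, and write all results (CSV/JSON/GraphML) plus a run
#' manifest to `out_dir`. Deterministic given config and inputs.
#'
#' @param config YAML path or list; see [read_run_config()]. Required
#'   keys: `topology` (and usually `trajectory`), `regions` (named lists
#'   of residue keys), `out_dir`. `path_pairs` is a list of two-element
#'   vectors of region names (default: all ordered region pairs).
#' @param traj Optionally, a pre-built `traj_ensemble` (the file inputs
#'   are then ignored); used by the simulate-then-analyze workflow.
#' @return Invisibly, a list with the in-memory results
#'   (`weights`, `graph`, `paths`, `centrality`, `block_stats`).
#' @export
run_network_pipeline <- function(config, traj = NULL) {
  config <- read_run_config(config, "network")
  out_dir <- config$out_dir %||% abort("Config needs `out_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  timings <- list()
  warnings <- character()
  note <- function(w) warnings <<- c(warnings, w)
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- withCallingHandlers(expr, warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    val
  }

  if (is.null(traj)) {
    if (is.null(config$topology)) abort("Config needs `topology` (or pass `traj`).")
    traj <- tick("load", load_trajectory(config$topology, config$trajectory,
                                         config$selection))
  }
  if (!is.null(config$last_frame) || config$first_frame > 1L) {
    traj <- traj_window(traj, config$first_frame,
                        config$last_frame %||% traj$n_frames)
  }
  if (config$stride > 1L) traj <- traj_stride(traj, config$stride)
  if (isTRUE(config$superpose)) {
    traj <- tick("superpose", superpose_frames(traj, selection = config$superpose_selection))
  }

  sigma <- solve_kernel_width(config$c, config$d_cut, config$kernel_target)
  cm <- tick("contact_map", compute_contact_map(traj, c = config$c, sigma = sigma))
  disp <- compute_displacements(traj)
  mi <- tick("mutual_information",
             estimate_mutual_information(disp, n_bins = config$n_bins,
                                         log_base = config$log_base))
  W <- build_weight_matrix(cm, mi, floor_eps = config$floor_eps,
                           log_base = config$log_base)

  block <- NULL
  if (!is.null(config$block_length)) {
    block <- tick("block_stats",
                  block_weight_std(traj, config$block_length,
                                   frame_time_ns = config$frame_time_ns,
                                   c = config$c, sigma = sigma,
                                   n_bins = config$n_bins,
                                   log_base = config$log_base,
                                   floor_eps = config$floor_eps))
  }

  graph <- build_graph(W, config$regions)
  pairs <- config$path_pairs
  if (!length(pairs) && length(config$regions) >= 2L) {
    nms <- names(graph$regions)
    pairs <- purrr::map(utils::combn(nms, 2, simplify = FALSE), identity)
  }
  paths_tbl <- tick("paths", purrr::map_dfr(pairs, function(pr) {
    minimal_path_length(graph, pr[[1]], pr[[2]]) |>
      mutate(source_region = pr[[1]], target_region = pr[[2]], .before = 1)
  }))
  centrality <- tick("centrality", betweenness_profile(graph))

  # outputs
  keys <- rownames(W$W)
  edge_tbl <- as_tibble(W)
  ij <- cbind(match(edge_tbl$from, keys), match(edge_tbl$to, keys))
  edge_tbl$C <- cm$C[ij]
  edge_tbl$M_norm <- mi$M_norm[ij]
  if (!is.null(block)) edge_tbl$sigma_w <- block$sigma_w[ij]

  outputs <- list(
    edges_csv = file.path(out_dir, "edges.csv"),
    weights_csv = file.path(out_dir, "weight_matrix.csv"),
    paths_csv = file.path(out_dir, "paths.csv"),
    paths_json = file.path(out_dir, "paths.json"),
    centrality_csv = file.path(out_dir, "centrality.csv"),
    graphml = file.path(out_dir, "graph.graphml")
  )
  write.csv(edge_tbl, outputs$edges_csv, row.names = FALSE)
  write.csv(as.data.frame(W$W), outputs$weights_csv, row.names = TRUE)
  write.csv(paths_tbl, outputs$paths_csv, row.names = FALSE)
  jsonlite::write_json(
    purrr::pmap(paths_tbl, function(source_region, target_region, subunit,
                                    d_min, reachable, path, ...) {
      list(source = source_region, target = target_region, subunit = subunit,
           reachable = reachable, d_min = d_min,
           nodes = if (is.na(path)) list() else strsplit(path, " - ", fixed = TRUE)[[1]])
    }),
    outputs$paths_json, auto_unbox = TRUE, digits = NA)
  write.csv(centrality, outputs$centrality_csv, row.names = FALSE)
  igraph::write_graph(graph$graph, outputs$graphml, format = "graphml")

  write_manifest(out_dir, config, outputs, timings, warnings)
  invisible(list(weights = W, contact_map = cm, mi = mi, graph = graph,
                 paths = paths_tbl, centrality = centrality,
                 block_stats = block))
}

#' Run the energetics pipeline
#'
#' From a table of Boltzmann fit parameters (CSV with columns
#' `construct`, `kind`, `z`, `z_se`, `v_half`, `v_half_se`), compute
#' gating free energies and mutant-minus-wild-type perturbations with
#' propagated errors, optionally correlate them against per-construct
#' network metrics, and write the tables plus a manifest.
#'
#' @param config YAML path or list; see [read_run_config()]. Keys:
#'   `fits_csv`, `wt`, `faraday`, `metrics_csv` (optional CSV with a
#'   `construct` column plus metric columns), `metric_columns` (which
#'   metric columns to correlate; default all numeric), `out_dir`.
#' @param fits Optionally, the fits as a tibble (overrides `fits_csv`).
#' @return Invisibly, a list with `energy_table` and `correlations`.
#' @export
run_energetics_pipeline <- function(config, fits = NULL) {
  config <- read_run_config(config, "energetics")
  out_dir <- config$out_dir %||% abort("Config needs `out_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  warnings <- character()

  if (is.null(fits)) {
    if (is.null(config$fits_csv)) abort("Config needs `fits_csv` (or pass `fits`).")
    fits <- as_tibble(read.csv(config$fits_csv))
  }
  if (nrow(fits) == 0L) {
    inform("Empty construct table: nothing to do.")
    write_manifest(out_dir, config, list(), timings, "empty construct table")
    return(invisible(list(energy_table = tibble(), correlations = tibble())))
  }
  t0 <- Sys.time()
  energy <- gating_energy_table(fits, wt = config$wt, faraday = config$faraday)
  timings$energetics <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)

  correlations <- tibble()
  if (!is.null(config$metrics_csv)) {
    metrics <- as_tibble(read.csv(config$metrics_csv))
    stopifnot("construct" %in% names(metrics))
    cols <- config$metric_columns %||%
      setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))], "construct")
    t0 <- Sys.time()
    correlations <- purrr::map_dfr(cols, function(cl) {
      purrr::map_dfr(unique(energy$kind), function(kd) {
        df <- energy |>
          filter(.data$kind == kd, .data$construct != config$wt) |>
          inner_join(metrics, by = "construct")
        if (nrow(df) < 3L || sd(df[[cl]]) == 0) return(tibble())
        correlate_metric_vs_energy(df[[cl]], df$ddg) |>
          mutate(metric = cl, kind = kd, .before = 1)
      })
    })
    timings$correlate <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }

  outputs <- list(
    energy_csv = file.path(out_dir, "gating_energies.csv"),
    correlation_json = file.path(out_dir, "correlations.json")
  )
  write.csv(energy, outputs$energy_csv, row.names = FALSE)
  jsonlite::write_json(correlations, outputs$correlation_json,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(out_dir, config, outputs, timings, warnings)
  invisible(list(energy_table = energy, correlations = correlations))
}
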