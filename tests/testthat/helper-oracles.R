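# Independent brute-force oracles for the graph arm, kept deliberately
# naive: exhaustive simple-path enumeration, no Dijkstra, no Brandes.

# Enumerate all simple paths s -> t in a weight matrix (NA = no edge).
# Returns list of integer node vectors.
enumerate_simple_paths <- function(W, s, t) {
  n <- nrow(W)
  out <- list()
  walk <- function(path, total) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- list(nodes = path, length = total)
      return()
    }
    for (u in seq_len(n)) {
      if (!is.na(W[v, u]) && !(u %in% path)) {
        walk(c(path, u), total + W[v, u])
      }
    }
  }
  walk(s, 0)
  out
}

# Brute-force minimum path length and optimal paths between node sets.
bf_region_shortest <- function(W, sources, targets, tol = 1e-9) {
  best_len <- Inf
  best_paths <- list()
  for (s in sources) for (t in targets) {
    if (s == t) {
      cand <- list(list(nodes = s, length = 0))
    } else {
      cand <- enumerate_simple_paths(W, s, t)
    }
    for (p in cand) {
      if (p$length < best_len - tol) {
        best_len <- p$length
        best_paths <- list(p$nodes)
      } else if (abs(p$length - best_len) <= tol) {
        best_paths <- c(best_paths, list(p$nodes))
      }
    }
  }
  list(length = best_len, paths = best_paths)
}

# Brute-force weighted betweenness (endpoints excluded, undirected pairs
# counted once), by enumerating all simple paths per pair.
bf_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    cand <- enumerate_simple_paths(W, s, t)
    if (!length(cand)) next
    lens <- vapply(cand, `[[`, numeric(1), "length")
    shortest <- cand[lens <= min(lens) + tol]
    sigma <- length(shortest)
    for (p in shortest) {
      interior <- setdiff(p$nodes, c(s, t))
      bc[interior] <- bc[interior] + 1 / sigma
    }
  }
  bc
}

# Random connected-ish undirected weighted graph as a symmetric matrix
# with NA off-edges.
random_weight_matrix <- function(n, p_edge = 0.5, names = NULL) {
  W <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 0.1, 2)
  }
  nms <- names %||% sprintf("A:%d", seq_len(n))
  dimnames(W) <- list(nms, nms)
  W
}

# Wrap an arbitrary non-negative symmetric weight matrix (NA = no edge)
# as the package's weight_matrix container.
wm_from_weights <- function(W) {
  mask <- !is.na(W)
  diag(mask) <- FALSE
  structure(list(W = W, edge_mask = mask, floor_eps = 1e-12, log_base = "e"),
            class = "weight_matrix")
}

# Closed-form Pearson correlation (textbook sums formula).
pearson_closed_form <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Eq.-style block standard deviation, re-implemented independently.
bf_block_sd <- function(w) {
  nb <- length(w)
  wbar <- sum(w) / nb
  sqrt(sum((w - wbar)^2) / (nb * (nb - 1)))
}
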