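#' Time-averaged contact map
#'
#' Averages the truncated Gaussian kernel of every C-alpha pair distance
#' over frames: `C_ij = mean_n K(d_ij(n))`. Entries lie in `[0, 1]`, the
#' matrix is exactly symmetric and the diagonal is 1.
#'
#' @param distances A `residues x residues x frames` distance array, as
#'   returned by [compute_ca_distances()], or a `traj_ensemble` (distances
#'   are then computed internally).
#' @param c Contact cut-off, Angstrom.
#' @param sigma Kernel width, Angstrom; default calibrated so the kernel
#'   is 1e-5 at 10 A.
#' @return A `contact_map` object with fields `C`, `c`, `sigma`,
#'   `n_frames_used`.
#' @export
compute_contact_map <- function(distances, c = 7.0,
                                sigma = solve_kernel_width(c, 10, 1e-5)) {
  if (inherits(distances, "traj_ensemble")) distances <- compute_ca_distances(distances)
  stopifnot(is.array(distances), length(dim(distances)) == 3L,
            dim(distances)[1] == dim(distances)[2], dim(distances)[3] >= 1L)
  K <- ifelse(distances <= c, 1, exp(-(distances^2 - c^2) / (2 * sigma^2)))
  C <- rowMeans(K, dims = 2)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- dimnames(distances)[1:2]
  structure(list(C = C, c = c, sigma = sigma, n_frames_used = dim(distances)[3]),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d residues, %d frames, c = %.2f A, sigma = %.3f A\n",
              nrow(x$C), x$n_frames_used, x$c, x$sigma))
  invisible(x)
}

# Shannon entropy of a count vector (nats).
count_entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Normalized mutual information of displacement series
#'
#' Plug-in (joint histogram) mutual information between every pair of
#' residue displacement series, normalized by the joint Shannon entropy
#' so values lie in `[0, 1]`. Each series is discretized on `n_bins`
#' equal-width bins spanning its own observed range; constant series have
#' zero entropy and get `M_norm = 0` with a warning.
#'
#' @param displacements A `frames x residues` matrix (columns named by
#'   residue key), e.g. from [compute_displacements()].
#' @param n_bins Number of equal-width bins per residue (>= 2).
#' @param log_base `"e"` (nats, default) or `"2"` (bits). The normalized
#'   ratio `M / H_joint` is base-invariant.
#' @return An `mi_matrix` object with fields `M`, `H_joint`, `M_norm`,
#'   `n_bins`, `log_base`.
#' @export
estimate_mutual_information <- function(displacements, n_bins = 20L,
                                        log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  stopifnot(is.matrix(displacements), nrow(displacements) >= 2L, n_bins >= 2L)
  n_bins <- as.integer(n_bins)
  nf <- nrow(displacements)
  nr <- ncol(displacements)
  keys <- colnames(displacements)

  bins <- matrix(1L, nf, nr)
  degenerate <- logical(nr)
  for (r in seq_len(nr)) {
    x <- displacements[, r]
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) {
      degenerate[r] <- TRUE
      next
    }
    b <- findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
    bins[, r] <- b
  }
  if (any(degenerate)) {
    warn(sprintf("%d constant displacement series: their M_norm is set to 0.",
                 sum(degenerate)))
  }

  H1 <- vapply(seq_len(nr), function(r) count_entropy(tabulate(bins[, r], n_bins)),
               numeric(1))
  M <- matrix(0, nr, nr, dimnames = list(keys, keys))
  Hj <- matrix(0, nr, nr, dimnames = list(keys, keys))
  for (i in seq_len(nr)) {
    bi <- bins[, i]
    for (j in i:nr) {
      joint <- tabulate(bi + n_bins * (bins[, j] - 1L), n_bins * n_bins)
      hij <- count_entropy(joint)
      mij <- max(H1[i] + H1[j] - hij, 0)
      Hj[i, j] <- Hj[j, i] <- hij
      M[i, j] <- M[j, i] <- mij
    }
  }
  scale <- if (log_base == "2") log(2) else 1
  M <- M / scale
  Hj <- Hj / scale
  Mn <- ifelse(Hj > 0, M / Hj, 0)
  Mn[degenerate, ] <- 0
  Mn[, degenerate] <- 0
  Mn <- pmin(pmax((Mn + t(Mn)) / 2, 0), 1)
  structure(list(M = M, H_joint = Hj, M_norm = Mn, n_bins = n_bins,
                 log_base = log_base),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  off <- x$M_norm[upper.tri(x$M_norm)]
  cat(sprintf("<mi_matrix> %d residues, %d bins, base %s; median off-diagonal M' = %.4f\n",
              nrow(x$M_norm), x$n_bins, x$log_base, median(off)))
  invisible(x)
}

#' Network edge weights from contacts and motion correlation
#'
#' Combines the contact map and the normalized mutual information into
#' the communication weight `w_ij = -log(C_ij * M'_ij)`: small when two
#' residues are both in contact and co-moving. Pairs whose product falls
#' below `floor_eps` carry no edge (no communication), so all retained
#' weights are finite and non-negative — the precondition for Dijkstra.
#'
#' @param contacts A `contact_map` or a numeric matrix in `[0, 1]`.
#' @param mi An `mi_matrix` or a numeric matrix in `[0, 1]` (normalized MI).
#' @param floor_eps Smallest product that still defines an edge.
#' @param log_base `"e"` or `"2"`; rescales weights, never path identity.
#' @return A `weight_matrix` object with fields `W` (NA off the edge set),
#'   `edge_mask`, `floor_eps`, `log_base`.
#' @export
build_weight_matrix <- function(contacts, mi, floor_eps = 1e-12,
                                log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  C <- if (inherits(contacts, "contact_map")) contacts$C else contacts
  Mn <- if (inherits(mi, "mi_matrix")) mi$M_norm else mi
  stopifnot(is.matrix(C), is.matrix(Mn), all(dim(C) == dim(Mn)))
  if (any(C < 0) || any(Mn < 0)) abort("Contact and MI matrices must be non-negative.")
  if (any(C > 1 + 1e-9) || any(Mn > 1 + 1e-9)) {
    abort("Contact and MI matrices must not exceed 1.")
  }
  A <- C * Mn
  A <- (A + t(A)) / 2
  mask <- A >= floor_eps
  diag(mask) <- FALSE
  scale <- if (log_base == "2") log(2) else 1
  W <- matrix(NA_real_, nrow(A), ncol(A), dimnames = dimnames(C) %||% dimnames(Mn))
  W[mask] <- pmax(-log(A[mask]) / scale, 0)
  structure(list(W = W, edge_mask = mask, floor_eps = floor_eps,
                 log_base = log_base),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d residues, %d edges (floor %.1e)\n",
              nrow(x$W), sum(x$edge_mask[upper.tri(x$edge_mask)]), x$floor_eps))
  invisible(x)
}

#' Edge list of a weight matrix
#'
#' @param x A `weight_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight` (one row per
#'   undirected edge).
#' @method as_tibble weight_matrix
#' @export
as_tibble.weight_matrix <- function(x, ...) {
  idx <- which(x$edge_mask & upper.tri(x$edge_mask), arr.ind = TRUE)
  keys <- rownames(x$W) %||% as.character(seq_len(nrow(x$W)))
  tibble(from = keys[idx[, 1]], to = keys[idx[, 2]],
         weight = x$W[idx])
}

#' Block-averaged standard deviation (trajectory block analysis)
#'
#' Applies the block formula
#' `sigma = sqrt( 1/(N_B (N_B - 1)) * sum_B (w_B - mean(w_B))^2 )`
#' to per-block values: the standard error of the block mean under the
#' assumption that blocks are uncorrelated.
#'
#' @param w_blocks A numeric vector of per-block values, or an array whose
#'   last dimension indexes blocks.
#' @return A scalar, or an array with the block dimension dropped. Any
#'   `NA` block propagates to `NA`.
#' @export
block_sd <- function(w_blocks) {
  f <- function(w) {
    nb <- length(w)
    if (nb < 2L) abort("Block analysis needs at least 2 blocks.")
    if (anyNA(w)) return(NA_real_)
    sqrt(sum((w - mean(w))^2) / (nb * (nb - 1)))
  }
  if (is.null(dim(w_blocks))) return(f(w_blocks))
  nd <- length(dim(w_blocks))
  apply(w_blocks, seq_len(nd - 1L), f)
}

#' Block-wise uncertainty of network weights
#'
#' Splits the trajectory into consecutive blocks, recomputes the full
#' weight pipeline (contact map, displacements about the block mean,
#' normalized MI, `-log` weights) independently in each block, and
#' returns the per-edge block standard deviation of `w_ij`. Pairs that
#' drop below the edge floor in any block get `NA`.
#'
#' @param traj A superposed `traj_ensemble`.
#' @param block_length Block length in frames; with `frame_time_ns` set,
#'   a length in nanoseconds is converted for you.
#' @param frame_time_ns Optional time per frame (ns) when `block_length`
#'   is given in ns.
#' @param c,sigma,n_bins,log_base,floor_eps Pipeline parameters, as in
#'   [compute_contact_map()], [estimate_mutual_information()] and
#'   [build_weight_matrix()].
#' @return A `block_stats` object with fields `sigma_w` (matrix),
#'   `block_weights` (array `residues x residues x n_blocks`), `n_blocks`,
#'   `block_length` (frames).
#' @export
block_weight_std <- function(traj, block_length, frame_time_ns = NULL,
                             c = 7.0, sigma = solve_kernel_width(c, 10, 1e-5),
                             n_bins = 20L, log_base = "e", floor_eps = 1e-12) {
  stopifnot(inherits(traj, "traj_ensemble"))
  if (!is.null(frame_time_ns)) block_length <- block_length / frame_time_ns
  block_length <- as.integer(round(block_length))
  if (block_length < 2L) abort("`block_length` must be at least 2 frames.")
  if (block_length > traj$n_frames) {
    abort("Block longer than the trajectory.")
  }
  n_blocks <- traj$n_frames %/% block_length
  if (n_blocks < 2L) abort("Trajectory too short for 2 blocks of this length.")

  n_res <- nrow(traj$residues)
  keys <- residue_keys(traj)
  wb <- array(NA_real_, c(n_res, n_res, n_blocks),
              dimnames = list(keys, keys, NULL))
  for (b in seq_len(n_blocks)) {
    sub <- traj_window(traj, (b - 1L) * block_length + 1L, b * block_length)
    cm <- compute_contact_map(sub, c = c, sigma = sigma)
    disp <- compute_displacements(sub)
    mi <- suppressWarnings(
      estimate_mutual_information(disp, n_bins = n_bins, log_base = log_base)
    )
    w <- build_weight_matrix(cm, mi, floor_eps = floor_eps, log_base = log_base)
    wb[, , b] <- w$W
  }
  sigma_w <- block_sd(wb)
  structure(list(sigma_w = sigma_w, block_weights = wb, n_blocks = n_blocks,
                 block_length = block_length),
            class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf("<block_stats> %d blocks of %d frames; median edge sigma = %.4f\n",
              x$n_blocks, x$block_length,
              median(x$sigma_w[upper.tri(x$sigma_w)], na.rm = TRUE)))
  invisible(x)
}
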