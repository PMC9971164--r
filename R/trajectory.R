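#' Trajectory ensemble container
#'
#' Per-frame C-alpha and side-chain center-of-mass coordinates for a set of
#' residues, the two feature streams the communication network is built
#' from. Coordinates are stored as `frames x residues x 3` arrays in
#' Angstrom; residues are identified by `(chain, resno)` with author
#' numbering preserved.
#'
#' @param residues Tibble with columns `chain`, `resno`, `resname`.
#' @param ca,sc Numeric arrays `frames x residues x 3` (Angstrom): C-alpha
#'   positions and side-chain heavy-atom centers of mass.
#' @return An object of class `traj_ensemble`.
#' @export
trajectory_ensemble <- function(residues, ca, sc) {
  residues <- as_tibble(residues)
  stopifnot(all(c("chain", "resno", "resname") %in% names(residues)))
  if (anyDuplicated(residues[c("chain", "resno")]) > 0) {
    abort("Duplicate (chain, resno) residue keys.")
  }
  if (!is.array(ca) || length(dim(ca)) != 3L || dim(ca)[3] != 3L) {
    abort("`ca` must be a frames x residues x 3 array.")
  }
  if (!identical(dim(ca), dim(sc))) abort("`ca` and `sc` must have identical dimensions.")
  if (dim(ca)[2] != nrow(residues)) abort("Residue count mismatch between metadata and coordinates.")
  if (!all(is.finite(ca)) || !all(is.finite(sc))) abort("Coordinates must be finite.")
  structure(
    list(residues = residues, ca = ca, sc = sc, n_frames = dim(ca)[1]),
    class = "traj_ensemble"
  )
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf(
    "<traj_ensemble> %d frames, %d residues (%d chain%s)\n",
    x$n_frames, nrow(x$residues),
    length(unique(x$residues$chain)),
    if (length(unique(x$residues$chain)) == 1) "" else "s"
  ))
  invisible(x)
}

#' Residue keys of a trajectory
#'
#' Stable node identifiers of the form `"<chain>:<resno>"` used throughout
#' the network arm.
#'
#' @param x A `traj_ensemble`, or a tibble with `chain` and `resno` columns.
#' @return Character vector of residue keys.
#' @export
residue_keys <- function(x) {
  res <- if (inherits(x, "traj_ensemble")) x$residues else x
  paste0(res$chain, ":", res$resno)
}

#' Subset trajectory frames
#'
#' `traj_stride()` keeps every `k`-th frame; `traj_window()` keeps frames
#' `first:last`. Both preserve residue metadata.
#'
#' @param traj A `traj_ensemble`.
#' @param k Stride (keep frames 1, 1+k, 1+2k, ...).
#' @param first,last Frame window bounds (1-based, inclusive).
#' @return A `traj_ensemble`.
#' @export
traj_stride <- function(traj, k) {
  stopifnot(inherits(traj, "traj_ensemble"), k >= 1)
  idx <- seq(1L, traj$n_frames, by = as.integer(k))
  trajectory_ensemble(traj$residues, traj$ca[idx, , , drop = FALSE],
                      traj$sc[idx, , , drop = FALSE])
}

#' @rdname traj_stride
#' @export
traj_window <- function(traj, first = 1L, last = traj$n_frames) {
  stopifnot(inherits(traj, "traj_ensemble"),
            first >= 1, last <= traj$n_frames, first <= last)
  idx <- seq(as.integer(first), as.integer(last))
  trajectory_ensemble(traj$residues, traj$ca[idx, , , drop = FALSE],
                      traj$sc[idx, , , drop = FALSE])
}

# Atomic masses from bio3d's periodic-table dataset (loaded explicitly:
# the dataset is not lazy-loaded through the namespace).
element_masses <- function(ele) {
  e <- new.env()
  utils::data("elements", package = "bio3d", envir = e)
  m <- e$elements$mass[match(ele, e$elements$symb)]
  m[is.na(m)] <- 12.0107
  m
}

# Parse a selection of the form "A" or "A:10-50" or "A:10-50,B:5-20" into a
# logical index over the residue table. NULL selects everything.
match_selection <- function(residues, selection) {
  if (is.null(selection)) return(rep(TRUE, nrow(residues)))
  if (is.logical(selection) && length(selection) == nrow(residues)) return(selection)
  keep <- rep(FALSE, nrow(residues))
  for (part in strsplit(selection, ",", fixed = TRUE)[[1]]) {
    bits <- strsplit(trimws(part), ":", fixed = TRUE)[[1]]
    ch <- bits[1]
    hit <- residues$chain == ch
    if (length(bits) > 1L) {
      rng <- as.integer(strsplit(bits[2], "-", fixed = TRUE)[[1]])
      if (length(rng) == 1L) rng <- c(rng, rng)
      hit <- hit & residues$resno >= rng[1] & residues$resno <= rng[2]
    }
    keep <- keep | hit
  }
  if (!any(keep)) abort(sprintf("Selection '%s' matches zero residues.", selection))
  keep
}

#' Load a structure + trajectory as residue features
#'
#' Reads a PDB topology and (optionally) a DCD or multi-model PDB
#' coordinate file, and reduces each frame to the two per-residue feature
#' streams used downstream: the C-alpha position and the mass-weighted
#' center of mass of the side-chain heavy atoms. Residues with no
#' side-chain heavy atoms (glycine) fall back to the C-alpha position.
#' Hydrogens are always ignored.
#'
#' @param topology_path Path to a PDB file defining atoms and residues.
#' @param coords_path Optional path to a DCD trajectory or a multi-model
#'   PDB; when `NULL` the topology's own coordinates form a single frame.
#' @param selection Optional residue selection string, e.g. `"A:10-50"` or
#'   `"A,B"`; `NULL` keeps all protein residues with a C-alpha.
#' @return A [trajectory_ensemble()].
#' @export
load_trajectory <- function(topology_path, coords_path = NULL, selection = NULL) {
  if (!file.exists(topology_path)) abort(sprintf("Topology '%s' not found.", topology_path))
  pdb <- bio3d::read.pdb(topology_path, verbose = FALSE)
  atoms <- pdb$atom

  if (is.null(coords_path)) {
    xyz <- matrix(pdb$xyz[1, ], nrow = 1)
  } else if (!file.exists(coords_path)) {
    abort(sprintf("Coordinate file '%s' not found.", coords_path))
  } else if (grepl("\\.dcd$", coords_path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(coords_path, verbose = FALSE)
    xyz <- matrix(xyz, nrow = nrow(xyz))
  } else {
    multi <- bio3d::read.pdb(coords_path, multi = TRUE, verbose = FALSE)
    xyz <- matrix(multi$xyz, nrow = nrow(multi$xyz))
  }
  if (ncol(xyz) != 3L * nrow(atoms)) {
    abort(sprintf(
      "Atom-count mismatch: topology has %d atoms, coordinates have %g.",
      nrow(atoms), ncol(xyz) / 3
    ))
  }

  elements <- bio3d::atom2ele(atoms$elety, rescue = TRUE)
  heavy <- elements != "H"
  backbone <- atoms$elety %in% c("N", "CA", "C", "O", "OXT")
  masses <- element_masses(elements)

  res_tab <- atoms |>
    mutate(.row = dplyr::row_number()) |>
    filter(.data$elety == "CA") |>
    distinct(.data$chain, .data$resno, .keep_all = TRUE)
  residues <- tibble(chain = res_tab$chain, resno = res_tab$resno,
                     resname = res_tab$resid)
  keep <- match_selection(residues, selection)
  residues <- residues[keep, ]
  res_tab <- res_tab[keep, ]
  n_res <- nrow(residues)
  n_frames <- nrow(xyz)

  ca <- array(NA_real_, c(n_frames, n_res, 3))
  sc <- array(NA_real_, c(n_frames, n_res, 3))
  col3 <- function(i) c(3 * (i - 1) + 1, 3 * (i - 1) + 2, 3 * i)
  for (r in seq_len(n_res)) {
    ca_row <- res_tab$.row[r]
    ca[, r, ] <- xyz[, col3(ca_row), drop = FALSE]
    in_res <- atoms$chain == residues$chain[r] & atoms$resno == residues$resno[r]
    sc_rows <- which(in_res & heavy & !backbone)
    if (length(sc_rows) == 0L) {
      sc[, r, ] <- ca[, r, ]  # glycine fallback: C-alpha stands in for the COM
    } else {
      w <- masses[sc_rows] / sum(masses[sc_rows])
      for (k in 1:3) {
        cols <- 3 * (sc_rows - 1) + k
        sc[, r, k] <- xyz[, cols, drop = FALSE] %*% w
      }
    }
  }
  trajectory_ensemble(residues, ca, sc)
}

#' Rigid-body superposition of trajectory frames
#'
#' Least-squares (Kabsch) superposition of every frame onto a reference
#' over the C-alpha atoms of a selection, applied jointly to the C-alpha
#' and side-chain streams so internal geometry is untouched. By default
#' the reference is the time-average structure and the fit is iterated
#' (fit, re-average, fit) so displacements are not dominated by
#' rigid-body drift.
#'
#' @param traj A `traj_ensemble`.
#' @param reference_frame Integer frame index used as reference, or
#'   `"average"` (default) for the iterated mean structure.
#' @param selection Residue selection string for the fitted C-alphas
#'   (`NULL` = all residues).
#' @param iterations Number of fit/re-average passes when
#'   `reference_frame = "average"`.
#' @return A superposed `traj_ensemble`.
#' @export
superpose_frames <- function(traj, reference_frame = "average",
                             selection = NULL, iterations = 2L) {
  stopifnot(inherits(traj, "traj_ensemble"))
  keep <- match_selection(traj$residues, selection)
  if (sum(keep) < 3L) abort("Superposition needs at least 3 selected residues.")
  n_res <- nrow(traj$residues)
  n_frames <- traj$n_frames

  # points per frame: CA block then SC block
  pts <- array(NA_real_, c(n_frames, 2 * n_res, 3))
  pts[, seq_len(n_res), ] <- traj$ca
  pts[, n_res + seq_len(n_res), ] <- traj$sc
  fit_pts <- which(keep)

  align_all <- function(pts, ref_fit) {
    # ref_fit: (n_fit x 3) reference coordinates of the fitted CA set
    ref_cen <- colMeans(ref_fit)
    ref0 <- sweep(ref_fit, 2, ref_cen)
    for (f in seq_len(n_frames)) {
      P <- pts[f, fit_pts, ]
      p_cen <- colMeans(P)
      H <- crossprod(sweep(P, 2, p_cen), ref0)
      s <- svd(H)
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      moved <- sweep(pts[f, , ], 2, p_cen) %*% t(R)
      pts[f, , ] <- sweep(moved, 2, ref_cen, "+")
    }
    pts
  }

  if (identical(reference_frame, "average")) {
    for (it in seq_len(max(1L, iterations))) {
      ref_fit <- apply(pts[, fit_pts, , drop = FALSE], c(2, 3), mean)
      pts <- align_all(pts, ref_fit)
    }
  } else {
    stopifnot(is.numeric(reference_frame), reference_frame >= 1,
              reference_frame <= n_frames)
    pts <- align_all(pts, pts[as.integer(reference_frame), fit_pts, ])
  }

  trajectory_ensemble(traj$residues,
                      pts[, seq_len(n_res), , drop = FALSE],
                      pts[, n_res + seq_len(n_res), , drop = FALSE])
}

#' Per-frame C-alpha distance matrices
#'
#' @param traj A `traj_ensemble`.
#' @return A `residues x residues x frames` array of Euclidean C-alpha
#'   distances (Angstrom); symmetric with zero diagonal in every frame.
#' @export
compute_ca_distances <- function(traj) {
  stopifnot(inherits(traj, "traj_ensemble"))
  n_res <- nrow(traj$residues)
  keys <- residue_keys(traj)
  out <- array(0, c(n_res, n_res, traj$n_frames),
               dimnames = list(keys, keys, NULL))
  for (f in seq_len(traj$n_frames)) {
    out[, , f] <- as.matrix(stats::dist(traj$ca[f, , ]))
  }
  out
}

#' Side-chain displacement series
#'
#' For each residue, the deviation of its side-chain center of mass from
#' its time-average position over the analyzed window. The default
#' (`mode = "magnitude"`) returns the scalar Euclidean norm of the
#' deviation per frame, the series whose pairwise mutual information
#' defines the correlation factor of the network; `mode = "components"`
#' keeps the 3D deviation vectors for sensitivity analyses.
#'
#' @param traj A superposed `traj_ensemble` with at least 2 frames.
#' @param mode `"magnitude"` (frames x residues matrix) or
#'   `"components"` (frames x residues x 3 array).
#' @return See `mode`; columns are named by residue key.
#' @export
compute_displacements <- function(traj, mode = c("magnitude", "components")) {
  stopifnot(inherits(traj, "traj_ensemble"))
  mode <- match.arg(mode)
  if (traj$n_frames < 2L) abort("Displacements need at least 2 frames.")
  mean_pos <- apply(traj$sc, c(2, 3), mean)
  dev <- sweep(traj$sc, c(2, 3), mean_pos, "-")
  keys <- residue_keys(traj)
  if (mode == "components") {
    dimnames(dev) <- list(NULL, keys, c("x", "y", "z"))
    return(dev)
  }
  out <- sqrt(dev[, , 1]^2 + dev[, , 2]^2 + dev[, , 3]^2)
  out <- matrix(out, nrow = traj$n_frames,
                dimnames = list(NULL, keys))
  out
}
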