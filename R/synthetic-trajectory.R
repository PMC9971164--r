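#' Specification for a planted-chain synthetic trajectory
#'
#' Describes a toy protein in which a chosen chain of residues shares a
#' common latent side-chain motion (a kinematic chain) embedded among
#' residues that move with independent noise only. Downstream, the
#' network pipeline should recover the chain as the minimal path between
#' its endpoints; the generator therefore carries its own ground truth.
#'
#' Geometry: residues sit on a jittered cubic lattice with spacing
#' `spatial_spacing` so that lattice neighbours are within the contact
#' cut-off (rich off-chain contact routes) while most pairs are beyond
#' it; the planted chain occupies consecutive sites of one lattice row.
#'
#' @param n_residues Total number of residues.
#' @param chain_indices Ordered, distinct 1-based residue indices forming
#'   the planted path.
#' @param coupling_strength Fraction in `[0, 1]` of the shared latent
#'   motion mixed into each chain residue's side-chain displacement.
#' @param spatial_spacing Distance (Angstrom) between consecutive chain
#'   residues (and lattice neighbours); must be at least 0.5 A.
#' @param noise_sd Per-frame independent Gaussian noise SD (Angstrom) on
#'   every side chain.
#' @param n_frames Number of frames to generate.
#' @param seed RNG seed; same seed, same trajectory.
#' @return A `chain_plant_spec` list.
#' @export
chain_plant_spec <- function(n_residues = 30L, chain_indices = 1:6,
                             coupling_strength = 0.8, spatial_spacing = 6.0,
                             noise_sd = 0.3, n_frames = 2000L, seed = 1L) {
  chain_indices <- as.integer(chain_indices)
  if (anyDuplicated(chain_indices) > 0) abort("`chain_indices` must be distinct.")
  if (any(chain_indices < 1L) || any(chain_indices > n_residues)) {
    abort("`chain_indices` must lie in [1, n_residues].")
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    abort("`coupling_strength` must lie in [0, 1].")
  }
  if (spatial_spacing < 0.5) {
    abort("Geometry error: chain residues closer than 0.5 Angstrom.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (n_frames < 2) abort("`n_frames` must be at least 2.")
  structure(
    list(n_residues = as.integer(n_residues), chain_indices = chain_indices,
         coupling_strength = coupling_strength, spatial_spacing = spatial_spacing,
         noise_sd = noise_sd, n_frames = as.integer(n_frames),
         seed = as.integer(seed)),
    class = "chain_plant_spec"
  )
}

# First-order autoregressive latent signal with unit stationary SD.
ar1_series <- function(n, phi = 0.9) {
  innov_sd <- sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1)
  eps <- rnorm(n - 1, sd = innov_sd)
  for (t in 2:n) x[t] <- phi * x[t - 1] + eps[t - 1]
  x
}

# Lattice site coordinates for n residues: the chain occupies consecutive
# x-positions of the first row; remaining residues fill the lattice in
# row-major order.
plant_lattice <- function(spec) {
  k <- length(spec$chain_indices)
  nx <- max(k, ceiling(spec$n_residues^(1 / 3)))
  ny <- ceiling(sqrt(spec$n_residues / nx))
  nz <- ceiling(spec$n_residues / (nx * ny))
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  grid <- grid[order(grid$z, grid$y, grid$x), , drop = FALSE]
  sites <- as.matrix(grid[seq_len(spec$n_residues), ]) * spec$spatial_spacing

  pos <- matrix(NA_real_, spec$n_residues, 3)
  pos[spec$chain_indices, ] <- sites[seq_len(k), , drop = FALSE]
  pos[-spec$chain_indices, ] <- sites[-seq_len(k), , drop = FALSE]
  pos
}

#' Generate a planted-chain trajectory
#'
#' Side-chain displacement of every chain residue is
#' `coupling_strength * s(t) + noise`, with `s(t)` a shared 3D AR(1)
#' latent signal (lag-1 correlation 0.9, stationary SD 1 A); non-chain
#' residues receive independent noise only. C-alphas carry a small
#' independent jitter (0.15 A) around fixed lattice sites so the contact
#' map is essentially static. Reproducible given `spec$seed`.
#'
#' @param spec A [chain_plant_spec()].
#' @return A [trajectory_ensemble()] with attribute `ground_truth` set to
#'   `spec`.
#' @export
generate_chain_trajectory <- function(spec) {
  stopifnot(inherits(spec, "chain_plant_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  f <- spec$n_frames
  base <- plant_lattice(spec)

  # fixed outward side-chain offset, 1.5 A, direction varying by residue
  theta <- runif(n, 0, 2 * pi); phi_ang <- acos(runif(n, -1, 1))
  offset <- 1.5 * cbind(sin(phi_ang) * cos(theta), sin(phi_ang) * sin(theta),
                        cos(phi_ang))

  latent <- cbind(ar1_series(f), ar1_series(f), ar1_series(f))
  ca <- array(rnorm(f * n * 3, sd = 0.15), c(f, n, 3))
  sc <- array(rnorm(f * n * 3, sd = spec$noise_sd), c(f, n, 3))
  for (k in 1:3) {
    ca[, , k] <- sweep(ca[, , k, drop = FALSE], 2, base[, k], "+")[, , 1]
    sck <- sweep(sc[, , k, drop = FALSE], 2, base[, k] + offset[, k], "+")[, , 1]
    sck[, spec$chain_indices] <- sck[, spec$chain_indices] +
      spec$coupling_strength * latent[, k]
    sc[, , k] <- sck
  }

  residues <- tibble(
    chain = "A", resno = seq_len(n),
    resname = ifelse(seq_len(n) %in% spec$chain_indices, "LEU", "ALA")
  )
  traj <- trajectory_ensemble(residues, ca, sc)
  attr(traj, "ground_truth") <- spec
  traj
}

# Minimal CHARMM-format DCD writer (little-endian, no unit cell). No
# installed R package writes DCD; bio3d reads this format back.
write_dcd <- function(coords, path) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wi(84L)
  writeChar("CORD", con, 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  # timestep (AKMA units) stored as the float bit pattern in slot 10
  icntrl[10] <- readBin(writeBin(1.0, raw(), size = 4, endian = "little"),
                        "integer", size = 4, endian = "little")
  icntrl[20] <- 24L
  wi(icntrl); wi(84L)
  title <- sprintf("%-80s", "written by gatingnet")
  wi(84L + 0L); wi(1L)  # title block: 4 + 80 bytes
  writeChar(substr(title, 1, 80), con, 80, eos = NULL)
  wi(84L)
  wi(4L); wi(na); wi(4L)
  for (fr in seq_len(nf)) {
    for (k in 1:3) {
      wi(4L * na)
      writeBin(as.numeric(coords[fr, , k]), con, size = 4, endian = "little")
      wi(4L * na)
    }
  }
  invisible(path)
}

#' Write a trajectory as PDB topology + DCD coordinates
#'
#' Each residue contributes two pseudo-atoms, `CA` (the C-alpha stream)
#' and `CB` (the side-chain center of mass), so that [load_trajectory()]
#' reads the fixture back through the real PDB/DCD parsers. A JSON
#' sidecar records the generating spec when the trajectory carries one.
#'
#' @param traj A `traj_ensemble`.
#' @param pdb_path,dcd_path Output file paths.
#' @param json_path Optional ground-truth sidecar path; defaults to
#'   `dcd_path` with a `.json` extension when the trajectory has a
#'   `ground_truth` attribute.
#' @return Invisibly, a list of the written paths.
#' @export
write_trajectory <- function(traj, pdb_path, dcd_path,
                             json_path = sub("\\.dcd$", ".json", dcd_path)) {
  stopifnot(inherits(traj, "traj_ensemble"))
  n_res <- nrow(traj$residues)
  n_atoms <- 2L * n_res
  # atom order: per residue, CA then CB
  coords <- array(NA_real_, c(traj$n_frames, n_atoms, 3))
  coords[, 2 * seq_len(n_res) - 1, ] <- traj$ca
  coords[, 2 * seq_len(n_res), ] <- traj$sc

  xyz1 <- as.vector(t(coords[1, , ]))
  bio3d::write.pdb(
    file = pdb_path, xyz = xyz1,
    resno = rep(traj$residues$resno, each = 2),
    resid = rep(traj$residues$resname, each = 2),
    chain = rep(traj$residues$chain, each = 2),
    elety = rep(c("CA", "CB"), n_res)
  )
  write_dcd(coords, dcd_path)
  gt <- attr(traj, "ground_truth")
  if (!is.null(gt) && !is.null(json_path)) {
    jsonlite::write_json(unclass(gt), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(pdb = pdb_path, dcd = dcd_path,
                 json = if (!is.null(gt)) json_path else NULL))
}
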