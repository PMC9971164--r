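# Shared fixture builders. Everything is generated in code at test time.

# Full network pipeline on a trajectory: superpose -> contact map ->
# displacements -> MI -> weights -> graph.
run_network_arm <- function(traj, c = 7, n_bins = 20, superpose = TRUE) {
  if (superpose) traj <- superpose_frames(traj)
  cm <- compute_contact_map(traj, c = c)
  disp <- compute_displacements(traj)
  mi <- suppressWarnings(estimate_mutual_information(disp, n_bins = n_bins))
  W <- build_weight_matrix(cm, mi)
  build_graph(W)
}

# Minimal path of a planted-chain trajectory between the chain endpoints.
recovered_chain <- function(spec) {
  traj <- generate_chain_trajectory(spec)
  g <- run_network_arm(traj)
  keys <- residue_keys(traj)
  shortest_path(g, keys[spec$chain_indices[1]],
                keys[spec$chain_indices[length(spec$chain_indices)]])
}

# Hand-built tiny trajectory: explicit coordinates, one residue per key.
toy_traj <- function(ca, sc = ca, chains = "A") {
  n_res <- dim(ca)[2]
  trajectory_ensemble(
    tibble::tibble(chain = rep_len(chains, n_res), resno = seq_len(n_res),
                   resname = "ALA"),
    ca, sc
  )
}

# Write a two-residue PDB (ALA with CB side chain, GLY with backbone only)
# for the glycine-fallback and identity round-trip tests.
write_ala_gly_pdb <- function(path) {
  xyz <- c(
    0, 0, 0,    # ALA N
    1, 0, 0,    # ALA CA
    2, 0, 0,    # ALA C
    3, 0, 0,    # ALA O
    1, 2, 0,    # ALA CB
    5, 0, 0,    # GLY N
    6, 0, 0,    # GLY CA
    7, 0, 0,    # GLY C
    8, 0, 0     # GLY O
  )
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = c(rep(1L, 5), rep(2L, 4)),
    resid = c(rep("ALA", 5), rep("GLY", 4)),
    chain = rep("A", 9),
    elety = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O")
  )
  path
}
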