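# Independent oracles and tiny fixtures used across the suite.

# Horn's quaternion closed-form optimal RMSD: independent of the package's
# SVD-based Kabsch implementation.
quaternion_rmsd_oracle <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(A, B)
  S <- function(i, j) M[i, j]
  K <- matrix(c(
    S(1,1)+S(2,2)+S(3,3), S(2,3)-S(3,2), S(3,1)-S(1,3), S(1,2)-S(2,1),
    S(2,3)-S(3,2), S(1,1)-S(2,2)-S(3,3), S(1,2)+S(2,1), S(3,1)+S(1,3),
    S(3,1)-S(1,3), S(1,2)+S(2,1), -S(1,1)+S(2,2)-S(3,3), S(2,3)+S(3,2),
    S(1,2)-S(2,1), S(3,1)+S(1,3), S(2,3)+S(3,2), -S(1,1)-S(2,2)+S(3,3)),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(A^2) + sum(B^2) - 2 * lam) / nrow(A), 0))
}

# Monte-Carlo rejection SASA: per atom, sample points uniformly on the
# expanded sphere and count those outside every other expanded sphere.
mc_sasa_oracle <- function(xyz, radii, probe, n_samples = 20000, seed = 1) {
  withr_seed <- function(code) redoxstruct::with_local_seed(seed, code)
  R <- radii + probe
  n <- nrow(xyz)
  withr_seed({
    vapply(seq_len(n), function(i) {
      pts <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
      pts <- pts / sqrt(rowSums(pts^2)) * R[i]
      pts <- sweep(pts, 2, xyz[i, ], "+")
      free <- rep(TRUE, n_samples)
      for (j in setdiff(seq_len(n), i)) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & d2 >= R[j]^2
      }
      4 * pi * R[i]^2 * mean(free)
    }, numeric(1))
  })
}

# A minimal single-residue PDB fixture with known printed coordinates.
ala_fixture_text <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 21.00           C",
    "ATOM      3  C   ALA A   1      10.729   6.844  -4.180  1.00 22.00           C",
    "ATOM      4  O   ALA A   1       9.580   7.133  -4.500  1.00 23.00           O",
    "ATOM      5  CB  ALA A   1      11.784   4.602  -4.713  1.00 24.00           C",
    "END"), collapse = "\n")
}

# A structure whose atoms sit at caller-chosen coordinates (one CA per
# residue), for exact-geometry checks.
point_structure <- function(xyz, chain = "A", resid = "ALA", b = 20) {
  n <- nrow(xyz)
  at <- data.frame(type = "ATOM", eleno = seq_len(n), elety = "CA", alt = "",
                   resid = resid, chain = chain, resno = seq_len(n), insert = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = b,
                   elesy = "C", solvent = FALSE, stringsAsFactors = FALSE)
  new_structure("points", at)
}

random_toy_structure <- function(seed) {
  with_local_seed(seed, {
    make_toy_structure(n_chains = sample(1:2, 1),
                       residues_per_chain = sample(5:15, 1),
                       jitter_sd = 0.2, seed = seed + 1000L)
  })
}

# serialize a trajectory to multi-model PDB text
trajectory_to_pdb <- function(tr) {
  lines <- character(0)
  for (k in seq_along(tr$frames)) {
    sk <- tr$topology
    sk$atoms[, c("x", "y", "z")] <- tr$frames[[k]]
    lines <- c(lines, sprintf("MODEL %8d", k), write_structure(sk), "ENDMDL")
  }
  lines
}

# A complete synthetic input set for the end-to-end pipeline.
write_fixture_inputs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dimer <- make_toy_structure(
    n_chains = 2, residues_per_chain = 15, seed = 21,
    chain_offsets = list(c(0, 0, 0), c(7, 1.5, 0)),
    cys_placements = list(
      list(chain = "A", resno = 4, partner = c("A", 6), distance = 2.05),
      list(chain = "A", resno = 11)))
  write_structure(dimer, file.path(dir, "dimer.pdb"))
  ch <- make_chromatogram(data.frame(center = c(10, 12, 14),
                                     width = c(0.3, 0.35, 0.4),
                                     area = c(1, 5.3, 3.7)),
                          baseline = 0.01, noise_sd = 0.02, seed = 22)
  write.table(data.frame(volume = ch$volume, absorbance = ch$absorbance),
              file.path(dir, "sec.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(Ve = c(9, 11, 13, 15, 17),
                         mass = c(670, 158, 44, 17, 1.35)),
              file.path(dir, "standards.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  tr <- make_loop_trajectory(n_frames = 60, dt = 0.2, core_size = 10,
                             motif_size = 8, transition_time = 6,
                             amplitudes = c(3, 4, 5, 6, 7, 8, 0, 0),
                             noise_sd = 0.3, seed = 23)
  writeLines(trajectory_to_pdb(tr), file.path(dir, "traj.pdb"))
  list(structure = file.path(dir, "dimer.pdb"),
       chromatogram = file.path(dir, "sec.csv"),
       standards = file.path(dir, "standards.csv"),
       trajectory = file.path(dir, "traj.pdb"))
}

full_config <- function(paths, out) {
  list(structure = paths$structure, chain = "A",
       chromatogram = paths$chromatogram, standards = paths$standards,
       n_peaks = 3, peak_centers = c(10, 12, 14),
       peak_labels = c("tetramer", "dimer", "monomer"),
       trajectory = paths$trajectory, trajectory_total_time = 11.8,
       motif = "11-18",
       titration = list(A412 = 0.283, protein_conc = 0.005, sd = 0.6),
       assay = list(dA340_per_min = 0.0622, assay_volume = 1,
                    enzyme_mass = 0.001),
       sasa = list(n_points = 240), seed = 7, output_dir = out)
}
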