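#!/usr/bin/env Rscript
# Generate the synthetic study inputs every later analysis step reads:
# a disulfide-bearing dimer, a rigidly moved homolog with a planted ligand,
# a 20 us mobile-motif trajectory with an abrupt concerted transition at
# 6 us, and SEC chromatograms at the wild-type-like and mutant-like
# oligomer compositions. All generators are seeded; planted ground truth is
# written alongside the files.

library(redoxstruct)

fixdir <- file.path("results", "fixtures")
dir.create(fixdir, recursive = TRUE, showWarnings = FALSE)

message("## 1. Dimer with planted thiol geometry")
# Chain A carries a covalent disulfide pair (2.05 A), a direct-exchange
# candidate pair (4.6 A), a rearrangement-tier pair (10.5 A) and one lone
# surface thiol; chain B packs against chain A to form an interface.
dimer <- make_toy_structure(
  n_chains = 2, residues_per_chain = 40, seed = 101,
  chain_offsets = list(c(0, 0, 0), c(7, 1.5, 0)),
  cys_placements = list(
    list(chain = "A", resno = 5, partner = c("A", 7), distance = 2.05),
    list(chain = "A", resno = 14, partner = c("A", 16), distance = 4.6),
    list(chain = "A", resno = 24, partner = c("A", 27), distance = 10.5),
    list(chain = "A", resno = 35)))
write_structure(dimer, file.path(fixdir, "dimer.pdb"))
message("   wrote dimer.pdb: ", structure_census(dimer)$n_atoms, " atoms, ",
        nrow(dimer$metadata$truth$pairs), " planted thiol pairs")

message("## 2. Homolog pair with a planted one-atom ligand")
target <- make_toy_structure(n_chains = 1, residues_per_chain = 40, seed = 102)
cb <- target$atoms[target$atoms$resno == 20 & target$atoms$elety == "CB", ]
lig_pos <- c(cb$x, cb$y, 0) / sqrt(cb$x^2 + cb$y^2) * 3.9 + c(cb$x, cb$y, cb$z)
lig <- data.frame(type = "HETATM", eleno = max(target$atoms$eleno) + 1L,
                  elety = "C1", alt = "", resid = "LIG", chain = "L",
                  resno = 1L, insert = "", x = lig_pos[1], y = lig_pos[2],
                  z = lig_pos[3], o = 1, b = 20, elesy = "C", solvent = FALSE)
holo_base <- new_structure("holo_base", rbind(target$atoms, lig))
hp <- make_homolog_pair(holo_base, axis = c(1, 2, 1), angle_deg = 55,
                        translation = c(15, -8, 4), noise_sd = 0.15, seed = 103)
write_structure(target, file.path(fixdir, "target.pdb"))
write_structure(hp$b, file.path(fixdir, "holo.pdb"))
message("   realized optimal-fit RMSD of the pair (truth): ",
        signif(hp$truth$rmsd, 4), " A")

message("## 3. 20 us trajectory with a concerted transition at 6 us")
amps <- c(seq(3, 15, length.out = 18), 0, 0)
tr <- make_loop_trajectory(n_frames = 200, dt = 0.1, core_size = 30,
                           motif_size = 20, transition_time = 6.0,
                           amplitudes = amps, noise_sd = 0.3, seed = 104)
lines <- character(0)
for (k in seq_along(tr$frames)) {
  sk <- tr$topology
  sk$atoms[, c("x", "y", "z")] <- tr$frames[[k]]
  lines <- c(lines, sprintf("MODEL %8d", k), write_structure(sk), "ENDMDL")
}
writeLines(lines, file.path(fixdir, "trajectory.pdb"))
message("   wrote trajectory.pdb: 200 frames, motif residues 31-50, ",
        "18 of 20 residues step at 6 us")

message("## 4. SEC chromatograms at study-like oligomer compositions")
# tetramer:dimer:monomer compositions observed for the wild type and the
# two serine mutants, planted as Gaussian peak areas (1% noise).
compositions <- list(WT = c(10, 53, 37), untreated = c(9, 48, 43),
                     C115S_like = c(42, 25, 33), C120S_like = c(29, 17, 54))
for (nm in names(compositions)) {
  a <- compositions[[nm]] / 10
  pk <- data.frame(center = c(10, 12, 14), width = c(0.3, 0.35, 0.4), area = a)
  pm <- max(pk$area / (pk$width * sqrt(2 * pi)))
  ch <- make_chromatogram(pk, baseline = 0.01, noise_sd = 0.01 * pm,
                          seed = 200 + match(nm, names(compositions)))
  write.table(data.frame(volume = ch$volume, absorbance = ch$absorbance),
              file.path(fixdir, paste0("sec_", nm, ".csv")),
              sep = ",", row.names = FALSE, quote = FALSE)
}
write.table(data.frame(Ve = c(9, 11, 13, 15, 17),
                       mass = c(670, 158, 44, 17, 1.35)),
            file.path(fixdir, "sec_standards.csv"),
            sep = ",", row.names = FALSE, quote = FALSE)
message("   wrote 4 chromatograms + calibration standards")

truth <- list(
  dimer_thiol_pairs = dimer$metadata$truth$pairs,
  homolog_rmsd = hp$truth$rmsd,
  trajectory = tr$topology$metadata$truth[c("transition_time",
                                            "transition_frame", "amplitudes",
                                            "motif_resno")],
  sec_compositions = compositions)
jsonlite::write_json(truth, file.path(fixdir, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Done: fixtures + truth.json under ", fixdir)
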