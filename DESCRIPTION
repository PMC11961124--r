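Package: redoxstruct
Title: Structural Analysis of Redox-Regulated Enzyme Conformation and Oligomerization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Structural-bioinformatics pipeline for redox-regulated enzymes of
    the Calvin-Benson-Bassham cycle, developed around the chloroplast
    sedoheptulose-1,7-bisphosphatase of Chlamydomonas reinhardtii. Reads
    PDB/mmCIF coordinates, multi-model trajectories and size-exclusion
    chromatograms; computes Kabsch superpositions and RMSD, Shrake-Rupley
    solvent accessible surface areas, cysteine redox-site classification
    reconciled with DTNB thiol titration, ligand-proximity active-site maps,
    interface buried areas and oligomeric assemblies, SEC calibration and
    Gaussian peak deconvolution, and molecular-dynamics mobile-motif
    analytics (per-residue RMSD, RMSF, concerted change-point detection,
    block medoids). Includes seeded synthetic-data generators with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
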