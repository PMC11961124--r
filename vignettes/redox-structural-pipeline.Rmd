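---
title: "Methods: structural analysis of a redox-regulated phosphatase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of a redox-regulated phosphatase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxstruct)
```

## Scope and scientific setting

`redoxstruct` implements the structural-analysis half of a study of a
redox-regulated Calvin–Benson–Bassham-cycle phosphatase: the chloroplast
sedoheptulose-1,7-bisphosphatase (SBPase) of *Chlamydomonas reinhardtii*.
The enzyme carries a regulatory disulfide (C115–C120) on a solvent-projected
loop-and-β-hairpin motif near the homodimer interface; its reduction
increases local disorder, changes the oligomer equilibrium, and — in
microsecond molecular-dynamics simulations — releases the motif in one
abrupt, concerted conformational transition. The package provides every
computation that analysis chain needs:

* coordinate and trajectory I/O (PDB, mmCIF, multi-model PDB) and
  two-column SEC chromatogram parsing;
* Kabsch least-squares superposition with sequence-based residue pairing
  and outlier trimming; distances, radius of gyration, b-factor profiles;
* Shrake–Rupley solvent accessible surface area (SASA) and
  exposed/buried classification;
* a cysteine redox census: disulfide detection, dithiol/disulfide exchange
  tiers, DTNB (Ellman) titration arithmetic and its reconciliation with the
  structural prediction, plus the coupled-assay specific activity;
* active-site mapping by ligand proximity after superposing a holo homolog;
* interface buried areas, assembly graphs, SEC calibration, Gaussian peak
  deconvolution and oligomer repartition, sequence mass/extinction;
* trajectory analytics: core superposition, per-residue RMSD series, pair
  distances, RMSF, concerted change-point detection, block medoids;
* seeded synthetic-data generators that plant known ground truth for all of
  the above.

The numbered scripts under `analysis/` run these steps as a narrative
workflow on the synthetic inputs; `run_report()` orchestrates the same
stages from one config.

## Superposition and RMSD

`superpose()` solves the orthogonal Procrustes problem by SVD (Kabsch),
constrained to proper rotations (det = +1, never a reflection; a
mirror-image input is still answered with the best proper rotation).
Near-degenerate (collinear) point sets are flagged but solved.
Cross-structure RMSD values in this field depend on an often-unstated
protocol, so the chain-level wrapper `superpose_chains()` fixes one and
reports both of its readings: CA atoms only, residues paired by global
sequence alignment (Needleman–Wunsch, BLOSUM62, gap 10/0.5), iterative
outlier trimming, with the trimmed and untrimmed RMSD both returned.

Trimming drops pairs whose residual exceeds `sigma_cutoff` (default 2.0)
times the **current RMSD**, for at most `max_cycles` (default 5) rounds,
never below 3 pairs, with an absolute floor of 1e-3 Å so numerically
identical inputs are not trimmed on noise. We deliberately scale the
rejection threshold by the RMSD rather than by the standard deviation of
the residuals: residuals after a rigid fit are non-negative and roughly
chi-distributed, so their SD sits below their mean and an SD-scaled
threshold cascades, discarding most of a perfectly good set. The
RMSD-scaled rule is the one structural-alignment tools commonly apply.

Correctness is checked against an independent closed form: Horn's
quaternion eigen-solution, which obtains the optimal-fit RMSD from the
largest eigenvalue of a 4×4 key matrix without constructing the rotation.
The two agree to better than 1e-8 Å across random instances.

## Solvent accessibility

`shrake_rupley()` samples each atom's probe-expanded sphere on a
deterministic golden-spiral lattice (default 960 points, probe 1.4 Å) and
counts points not occluded by any neighbor. The van der Waals table is
NACCESS-like (C 1.70, N 1.55, O 1.52, S 1.80 Å) and swappable. Determinism
matters here: the exposed/buried classification of individual SG atoms can
hinge on fractions of Å², and a quasi-random lattice makes those calls
reproducible. Quadrature quality: an isolated sphere is within 1% of
4π(r+probe)², doubling the lattice moves totals by <0.5%, and two-sphere
overlaps agree with a Monte-Carlo rejection oracle to ~2%. A floor of 100
lattice points is enforced.

A cysteine's SG is classed *exposed* when its SG-scoped area strictly
exceeds 0.05 Å². The threshold is intentionally tiny: in the reference
analysis the smallest area still classed exposed is ~0.11 Å², i.e. any
non-negligible SG area counts, and areas at or below the threshold are
buried. Accessibility is computed in the biological-dimer context (the
partner chain present) because the titration it must reconcile with was
performed on the native, predominantly dimeric protein; single-chain mode
is available by passing one chain's atoms.

## Cysteine redox census

`detect_disulfides()` reports SG–SG pairs within 2.3 Å (covalent S–S
≈ 2.05 Å plus coordinate error at ~3 Å resolution), greedily matched
nearest-first so each SG has at most one partner. Free-thiol pairs are
tiered as exchange candidates: *direct* within 5.0 Å (covers observed
3.5 and 4.6 Å pairs), *rearrangement* within 11.0 Å (covers 10.1 and
10.5 Å pairs that would need main-chain motion). These tier cutoffs are
this package's construction — the source analyses call such pairs
"plausible" without a number — so they are configurable and every report
carries the raw distances, ensuring no conclusion hinges on the defaults.

The predicted DTNB-reactive count is the number of exposed free thiols.
`dtnb_stoichiometry()` converts A412 to thiols/monomer with
ε(TNB⁻) = 14.15 mM⁻¹cm⁻¹, and `reconcile_titration()` declares the
structural prediction consistent when it falls within two standard
deviations of the titration. `specific_activity()` converts a coupled-assay
A340 slope to µmol(NADPH) min⁻¹ mg⁻¹ using ε(NADPH) = 6.22 mM⁻¹cm⁻¹
(the standard value; assays rarely restate it).

## Active-site transfer

`map_pocket_from_holo()` superposes the ligand-bearing homolog chain onto
the target chain (CA, sequence-paired, trimmed), carries the ligand atoms
through that transform, and lists target residues with any heavy atom
within the cutoff (default 4 Å) of any ligand atom. Because residue
correspondence comes from the sequence alignment, numbering offsets between
homolog and target cannot corrupt identities — a property tested with
renumbered fixtures. Pocket membership is monotone in the cutoff.
`site_distances()` reports min/mean/max CA distances from named residue
groups (e.g. phosphosite clusters) to a reference atom such as a
pocket-center water; where a reference atom's identity is ambiguous in the
source material, report the distances and let the reader judge, rather than
asserting a single number.

## Interfaces, assemblies and SEC

`buried_area()` uses the PISA-style convention
ASA(A) + ASA(B) − ASA(AB), all three terms computed with identical
parameters, clipped at zero and exactly symmetric in chain order.
`detect_assemblies()` scores all chain pairs and links those burying at
least 500 Å² — well under a biological dimer interface (~4000 Å²), above
crystal-packing noise — then labels connected components by size; raising
the threshold can only split, never merge, components.

SEC analysis: `sec_calibrate()` fits log10(mass) against elution volume
(or Kav when void/column volumes are given; slope must be negative on sane
standards, a positive slope is flagged). `deconvolve()` fits a sum of
symmetric Gaussians plus a constant baseline by Levenberg–Marquardt with
non-negative areas; non-convergence is flagged on the result, never
thrown. Peaks are parameterized directly by area, and `repartition()` turns
areas into percentages — peak *area*, not height, is used because
absorbance integrates to amount of protein; a height-based mode exists for
sensitivity analysis. Tailing shoulders are modeled as a second species
(symmetric Gaussians) rather than as an exponentially modified peak,
matching the interpretation of the shoulder as a distinct oligomer.
`mass_extinction()` uses standard average residue masses plus one water and
the 5500/1490/125 conventions for Trp/Tyr/cystine at 280 nm; both reduced
and cystine-paired extinctions are reported because tag sequences of real
constructs are often not recoverable from a paper.

## Trajectory analytics

`core_superpose()` fits every frame onto frame 1 over a rigid-core CA set
so mobile-motif series reflect internal motion, not tumbling. The default
reference frame is the first (the crystallographic starting conformation).
Per-residue RMSD series are heavy-atom, no per-residue refit.
`rmsf()` measures fluctuation about the window-mean position; isotropic
per-coordinate jitter of width σ gives σ√3, which the implementation
reproduces within 5% at 2000 frames.

Change points are found per residue by binary segmentation on segment
means: the split maximizing the between-segment contrast is accepted when
the mean shift reaches `min_jump` (default 1 Å) with both segments at least
`min_segment` (default 5) frames, then recursion continues on both sides.
We chose binary segmentation over Bayesian online detection because the
phenomenon of interest is a single abrupt, visually identified jump —
a deterministic, parameter-light method suffices and is exactly
reproducible. Transition times are clustered across residues by single
linkage with a `concert_window` of 0.5 µs, and an event is *concerted* when
at least `concert_fraction` = 0.75 of the mobile residues participate —
encoding "nearly all residues jump together" while tolerating the couple
of residues that sit still. `block_representative()` returns the medoid
frame of a time window under pairwise heavy-atom RMSD (ties to the earliest
frame); the clustering method behind published "representative structures"
is typically unstated, and a medoid is the simplest defensible choice —
it is verified against an exhaustive O(n²) search.

## Synthetic data: what it emulates, what it does not

The generators plant the signal shapes the real study analyzes, with
ground truth recorded in metadata so recovery can be scored without
re-derivation:

* `make_toy_structure()` — poly-alanine chains on a smooth helical curve,
  cysteines substituted at requested positions with SG–SG distances
  realized exactly (the paired SGs sit symmetrically on the CB–CB axis);
  multi-chain offsets create interfaces at will. Geometrically plausible,
  not physically minimized — adequate for geometry, accessibility and
  interface code paths, and stated openly.
* `make_homolog_pair()` — a rigid motion plus Gaussian coordinate noise,
  with the realized optimal-fit RMSD recorded by the quaternion closed
  form, independent of the Kabsch path it will test.
* `make_loop_trajectory()` — a rigid core plus a motif that steps along
  fixed random directions at a planted time, with jitter and optional
  global tumbling. Defaults mirror the study conditions: 20 µs span,
  20-residue motif, transition at 6 µs, per-residue amplitudes 3–15 Å with
  two silent residues, jitter 0.3 Å per coordinate.
* `make_chromatogram()` — sums of Gaussians plus baseline and noise; the
  study-like composition is tetramer:dimer:monomer = 10:53:37 at 1% of
  peak-maximum noise.

Each generator draws from its own locally seeded stream
(`with_local_seed()`), so calls compose and never disturb the caller's
RNG; identical arguments give bit-identical output.

What passing on these fixtures does **not** show: the toy backbone has no
real side-chain packing, so absolute SASA values and buried areas are not
comparable to a real protein's; the trajectory noise is isotropic Gaussian,
unlike correlated thermal motion; chromatogram peaks are strictly Gaussian.
The fixtures validate the *machinery* — the regression against the
deposited crystal structures (which requires fetching them from the PDB)
validates the numbers on real data, and runs whenever those files are
reachable.

## Problem sizes and numerical choices

Analyses and tests run on deliberately small problems: toy chains of 5–40
residues, trajectories of 100–2000 frames at 50–250 atoms, chromatograms of
~600 points, 100-replicate property studies — sizes chosen so the whole
validation suite re-runs in minutes on one CPU while still giving the
property tests real statistical teeth. Tolerances are stated per check:
1e-8 Å against the quaternion oracle, 1% against the analytic sphere, 2%
against Monte-Carlo areas, ±2 frames for change-point recovery in ≥95% of
100 seeded runs, <2% median error for SEC area recovery. Degenerate inputs
fail loudly (empty structures, non-monotonic volume axes, mismatched model
atom counts name the offending model) except where the contract says
otherwise (no cysteines is an empty report, a non-converged peak fit is a
flagged result).

## Known limitations

* No relative-ASA normalization (Gly-X-Gly reference) and no Lee–Richards
  slicing; exposure thresholds are absolute areas.
* Gaussian-only peak shapes; strongly tailing columns would bias areas.
* Binary segmentation assumes piecewise-constant means; slow drifts are
  not change points.
* No crystallographic symmetry expansion: assemblies are inferred within
  the asymmetric unit as deposited.
* Author residue numbering is trusted on parse; when cross-referencing a
  deposited entry against a sequence-database numbering, verify the offset
  on load (the sequence-based pairing makes the analyses robust to it).
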