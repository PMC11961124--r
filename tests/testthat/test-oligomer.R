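test_that("buried area is symmetric, zero for distant chains, and matches a Monte-Carlo oracle", {
  far <- make_toy_structure(n_chains = 2, residues_per_chain = 5, seed = 1)
  expect_equal(buried_area(far, "A", "B", n_points = 480)$buried_area, 0)

  docked <- make_toy_structure(n_chains = 2, residues_per_chain = 5, seed = 2,
                               chain_offsets = list(c(0, 0, 0), c(6.5, 1, 0.5)))
  ab <- buried_area(docked, "A", "B", n_points = 960)
  ba <- buried_area(docked, "B", "A", n_points = 960)
  expect_equal(ab$buried_area, ba$buried_area)
  expect_gt(ab$buried_area, 50)
  expect_true(all(c("A", "B") %in% ab$contacts$chain))

  vdw <- default_vdw_radii()
  mc_total <- function(at, seed) {
    sum(mc_sasa_oracle(as.matrix(at[, c("x", "y", "z")]),
                       radii = as.numeric(vdw[at$elesy]), probe = 1.4,
                       n_samples = 40000, seed = seed))
  }
  ata <- chain_atoms(docked, "A"); atb <- chain_atoms(docked, "B")
  oracle <- mc_total(ata, 101) + mc_total(atb, 102) - mc_total(rbind(ata, atb), 103)
  expect_equal(ab$buried_area, oracle, tolerance = 0.02)
})

test_that("assembly detection labels components and coarsens monotonically", {
  solo <- make_toy_structure(n_chains = 1, residues_per_chain = 5, seed = 1)
  ag1 <- detect_assemblies(solo, n_points = 240)
  expect_equal(ag1$labels, "monomer")

  two_far <- make_toy_structure(n_chains = 2, residues_per_chain = 5, seed = 1)
  ag2 <- detect_assemblies(two_far, n_points = 240)
  expect_equal(sort(ag2$labels), c("monomer", "monomer"))

  # four chains packed as two dimers
  tetra <- make_toy_structure(n_chains = 4, residues_per_chain = 5, seed = 3,
                              chain_offsets = list(c(0, 0, 0), c(6.5, 1, 0),
                                                   c(80, 0, 0), c(86.5, 1, 0)))
  ag4 <- detect_assemblies(tetra, threshold = 50, n_points = 240)
  expect_equal(sort(ag4$labels), c("dimer", "dimer"))
  comp_of <- function(ag, ch) which(vapply(ag$components, function(x) ch %in% x, logical(1)))
  expect_equal(comp_of(ag4, "A"), comp_of(ag4, "B"))
  expect_equal(comp_of(ag4, "C"), comp_of(ag4, "D"))
  # raising the threshold never merges components
  lo <- detect_assemblies(tetra, threshold = 50, n_points = 240)
  hi <- detect_assemblies(tetra, threshold = 1e5, n_points = 240)
  for (comp in hi$components) {
    holders <- vapply(comp, function(ch) comp_of(lo, ch), integer(1))
    expect_equal(length(unique(holders)), 1)
  }
})

test_that("SEC calibration recovers exact lines and matches the normal equations", {
  std <- data.frame(Ve = c(10, 12, 14, 16), mass = 10^(3 - 0.25 * c(10, 12, 14, 16)))
  cal <- sec_calibrate(std)
  expect_equal(cal$slope, -0.25, tolerance = 1e-12)
  expect_equal(cal$intercept, 3, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_false(cal$warning_positive_slope)

  two <- sec_calibrate(data.frame(Ve = c(10, 14), mass = c(100, 10)))
  expect_equal(as.numeric(apparent_mass(two, 10)), 100, tolerance = 1e-9)
  expect_equal(as.numeric(apparent_mass(two, 14)), 10, tolerance = 1e-9)

  with_local_seed(23, {
    Ve <- seq(9, 17, by = 1)
    y <- 3.2 - 0.22 * Ve + rnorm(length(Ve), sd = 0.05)
    noisy <- data.frame(Ve = Ve, mass = 10^y)
    cal2 <- sec_calibrate(noisy)
    X <- cbind(1, Ve)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # closed-form least squares
    expect_equal(cal2$intercept, beta[1], tolerance = 1e-9)
    expect_equal(cal2$slope, beta[2], tolerance = 1e-9)
  })
  expect_error(sec_calibrate(data.frame(Ve = c(10, 10), mass = c(1, 2))), "duplicate")
  expect_true(sec_calibrate(data.frame(Ve = c(10, 14), mass = c(10, 100)))$warning_positive_slope)
})

test_that("apparent mass round-trips through the calibration and flags extrapolation", {
  cal <- sec_calibrate(data.frame(Ve = c(10, 12, 14), mass = c(400, 100, 25)))
  Ve_of <- function(mass) (log10(mass) - cal$intercept) / cal$slope
  for (m in c(300, 80, 30))
    expect_equal(as.numeric(apparent_mass(cal, Ve_of(m))), m, tolerance = 1e-9)
  expect_true(attr(apparent_mass(cal, 20), "extrapolated"))
  expect_false(attr(apparent_mass(cal, 12), "extrapolated"))
  # Kav mode reproduces standards when column volumes are given
  calk <- sec_calibrate(data.frame(Ve = c(10, 12, 14), mass = c(400, 100, 25)),
                        V0 = 8, Vc = 24)
  expect_equal(calk$on, "Kav")
  expect_equal(as.numeric(apparent_mass(calk, 12)), 100, tolerance = 1e-9)
})

test_that("deconvolution recovers planted Gaussians", {
  # noiseless single peak: near-exact recovery
  one <- make_chromatogram(data.frame(center = 12, width = 0.4, area = 5),
                           baseline = 0.02, noise_sd = 0, seed = 1)
  fit1 <- deconvolve(one, 1, init_centers = 11.5)
  expect_true(fit1$converged)
  expect_equal(fit1$peaks$center, 12, tolerance = 1e-6)
  expect_equal(fit1$peaks$width, 0.4, tolerance = 1e-6)
  expect_equal(fit1$peaks$area, 5, tolerance = 5 * 1e-6)
  expect_equal(fit1$baseline, 0.02, tolerance = 1e-6)

  # three peaks at the published-like 10:53:37 composition, 1% noise
  peaks <- data.frame(center = c(10, 12, 14), width = c(0.3, 0.35, 0.4),
                      area = c(1.0, 5.3, 3.7))
  peak_max <- max(peaks$area / (peaks$width * sqrt(2 * pi)))
  tri <- make_chromatogram(peaks, baseline = 0.01, noise_sd = 0.01 * peak_max,
                           seed = 1)
  fit3 <- deconvolve(tri, 3, init_centers = c(9.7, 12.2, 13.8))
  expect_true(fit3$converged)
  expect_lt(max(abs(fit3$peaks$area - peaks$area) / peaks$area), 0.02)

  # overlapping shoulder one width apart: both resolved, total area conserved
  sh <- make_chromatogram(data.frame(center = c(12, 12.4), width = c(0.4, 0.4),
                                     area = c(4, 2)), noise_sd = 0, seed = 1)
  fits <- deconvolve(sh, 2, init_centers = c(11.8, 12.6))
  expect_equal(sum(fits$peaks$area), 6, tolerance = 0.01)
  expect_equal(sort(fits$peaks$center), c(12, 12.4), tolerance = 0.05)

  # parameter-recovery property across random compositions
  with_local_seed(37, {
    errs <- replicate(10, {
      a <- rgamma(3, 2); a <- a / sum(a) * 10
      pk <- data.frame(center = c(10, 12, 14), width = c(0.3, 0.35, 0.4), area = a)
      pm <- max(pk$area / (pk$width * sqrt(2 * pi)))
      ch <- make_chromatogram(pk, baseline = 0.01, noise_sd = 0.01 * pm,
                              seed = sample.int(1e6, 1))
      fit <- deconvolve(ch, 3, init_centers = c(9.8, 12.1, 14.2))
      max(abs(fit$peaks$area - a) / a)
    })
    expect_lt(median(errs), 0.02)
  })

  # baseline-only trace: flagged, not thrown
  flat <- make_chromatogram(data.frame(center = 12, width = 0.4, area = 0),
                            baseline = 0.05, noise_sd = 0, seed = 1)
  fit0 <- deconvolve(flat, 1, init_centers = 12)
  expect_true(!fit0$converged || all(fit0$peaks$area < 1e-6))
})

test_that("species repartition normalizes areas to percentages", {
  pm <- structure(list(peaks = data.frame(center = c(10, 12, 14),
                                          width = c(0.3, 0.35, 0.4),
                                          area = c(1.0, 5.3, 3.7)),
                       baseline = 0), class = "PeakModel")
  rp <- repartition(pm, c("tetramer", "dimer", "monomer"))
  expect_equal(rp$percent, c(10, 53, 37))
  expect_equal(sum(rp$percent), 100, tolerance = 1e-6)
  single <- structure(list(peaks = data.frame(center = 1, width = 1, area = 2)),
                      class = "PeakModel")
  expect_equal(repartition(single, "dimer")$percent, 100)
  even <- structure(list(peaks = data.frame(center = c(1, 2), width = c(1, 1),
                                            area = c(2, 2))), class = "PeakModel")
  expect_equal(repartition(even, c("a", "b"))$percent, c(50, 50))
  zero <- structure(list(peaks = data.frame(center = 1, width = 1, area = 0)),
                    class = "PeakModel")
  expect_error(repartition(zero, "a"), "zero total")
  expect_error(repartition(pm, c("a", "b")), "one label per peak")
})

test_that("sequence mass and extinction follow the standard conventions", {
  g <- mass_extinction("G")
  expect_equal(g$mass, 75.07, tolerance = 1e-2)
  w <- mass_extinction("W")
  expect_equal(w$epsilon_reduced, 5500)
  cc <- mass_extinction("CC")
  expect_equal(cc$epsilon_cystine - cc$epsilon_reduced, 125)
  expect_error(mass_extinction(""), "empty")
  expect_error(mass_extinction("GXZ"), "unknown residue")

  # additivity: concatenation adds masses minus one water per junction
  with_local_seed(41, {
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (k in 1:10) {
      a <- paste(sample(alphabet, sample(3:10, 1), replace = TRUE), collapse = "")
      b <- paste(sample(alphabet,
                        sample(3:10, 1), replace = TRUE), collapse = "")
      expect_equal(mass_extinction(paste0(a, b))$mass,
                   mass_extinction(a)$mass + mass_extinction(b)$mass - 18.01528,
                   tolerance = 1e-9)
    }
  })
  # independent cross-check against seqinr's protein molecular weight
  skip_if_not_installed("seqinr")
  seqs <- c("ACDEFGHIKLMNPQRSTVWY", "GGGG", "WYC")
  for (sq in seqs) {
    expect_equal(mass_extinction(sq)$mass,
                 seqinr::pmw(strsplit(sq, "")[[1]]), tolerance = 0.01)
  }
})
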