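test_that("superposition recovers exact rigid motions", {
  with_local_seed(42, {
    P <- matrix(rnorm(30), ncol = 3)
    # identity
    sp0 <- superpose(P, P)
    expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
    expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
    # 90 degrees about z plus translation
    Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Q <- P %*% t(Rz) + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
    sp <- superpose(P, Q)
    expect_lt(sp$rmsd, 1e-10)
    expect_equal(sp$rotation, t(Rz), tolerance = 1e-8)
    moved <- apply_superposition(P, sp)
    expect_lt(max(abs(moved - Q)), 1e-8)
  })
})

test_that("Kabsch RMSD matches the quaternion closed form on noisy pairs", {
  with_local_seed(7, {
    for (k in 1:30) {
      n <- sample(10:80, 1)
      A <- matrix(rnorm(3 * n), ncol = 3) * 10
      B <- A + matrix(rnorm(3 * n, sd = runif(1, 0.1, 2)), ncol = 3)
      expect_equal(superpose(A, B)$rmsd, quaternion_rmsd_oracle(A, B),
                   tolerance = 1e-8)
    }
  })
})

test_that("superposition RMSD is invariant under rigid pre-motions and never reflects", {
  with_local_seed(11, {
    A <- matrix(rnorm(60), ncol = 3) * 5
    B <- A + matrix(rnorm(60, sd = 0.5), ncol = 3)
    base <- superpose(A, B)$rmsd
    for (k in 1:20) {
      ax <- rnorm(3); ang <- runif(1, 0, 360)
      u <- ax / sqrt(sum(ax^2)); th <- ang * pi / 180
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      A2 <- A %*% t(R) + matrix(rnorm(3, sd = 10), 20, 3, byrow = TRUE)
      sp <- superpose(A2, B)
      expect_lt(abs(sp$rmsd - base), 1e-9)
      expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    }
    # a mirror-image pair must still yield a proper rotation
    M <- A; M[, 1] <- -M[, 1]
    expect_equal(det(superpose(M, A)$rotation), 1, tolerance = 1e-8)
    # near-collinear points are flagged degenerate but still solved
    line <- cbind(seq_len(10), 0, 0) + matrix(rnorm(30, sd = 1e-10), ncol = 3)
    expect_true(superpose(line, line)$degenerate)
  })
})

test_that("iterative trimming removes planted outlier pairs", {
  with_local_seed(3, {
    A <- matrix(rnorm(150), ncol = 3) * 8
    B <- A + matrix(rnorm(150, sd = 0.1), ncol = 3)
    B[1:3, ] <- B[1:3, ] + 10  # three displaced pairs
    plain <- superpose(A, B)
    trimmed <- superpose(A, B, trim = list(max_cycles = 5, sigma_cutoff = 2))
    expect_gt(plain$rmsd, 1)
    expect_lt(trimmed$rmsd, 0.25)
    expect_false(any(trimmed$kept[1:3]))
    expect_gte(trimmed$n_atoms, 40)
    expect_gt(trimmed$rmsd_all, trimmed$rmsd)
  })
})

test_that("atom distances obey symmetry, identity and the triangle inequality", {
  s <- make_toy_structure(residues_per_chain = 12, seed = 5,
                          cys_placements = list(list(chain = "A", resno = 3,
                                                     partner = c("A", 5),
                                                     distance = 5.00)))
  expect_equal(atom_distance(s, "A:3:SG", "A:5:SG"), 5.00, tolerance = 1e-9)
  expect_equal(atom_distance(s, "A:3:SG", "A:3:SG"), 0)
  with_local_seed(9, {
    for (k in 1:20) {
      ijk <- sample(1:12, 3)
      sel <- sprintf("A:%d:CA", ijk)
      dab <- atom_distance(s, sel[1], sel[2])
      expect_equal(dab, atom_distance(s, sel[2], sel[1]))
      expect_lte(dab, atom_distance(s, sel[1], sel[3]) +
                   atom_distance(s, sel[3], sel[2]) + 1e-12)
    }
  })
})

test_that("radius of gyration matches symmetry cases and the brute-force sum", {
  one <- point_structure(matrix(c(0, 0, 0), 1))
  expect_equal(radius_of_gyration(one), 0)
  two <- point_structure(matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(radius_of_gyration(two, weighting = "uniform"), 1.0)
  with_local_seed(21, {
    xyz <- matrix(rnorm(3000), ncol = 3) * 15
    s <- point_structure(xyz)
    ctr <- colMeans(xyz)
    oracle <- sqrt(sum(sweep(xyz, 2, ctr)^2) / nrow(xyz))
    expect_equal(radius_of_gyration(s, weighting = "uniform"), oracle,
                 tolerance = 1e-9)
  })
  empty <- one; empty$atoms <- empty$atoms[0, ]
  expect_error(radius_of_gyration(empty), "empty")
})

test_that("b-factor profiles average per residue and expose planted mobility", {
  s <- make_toy_structure(residues_per_chain = 15, seed = 2)
  prof <- bfactor_profile(s, "A")
  expect_true(all(prof$b_mean == 20))
  # residue whose atom b-factors average 20 -> mean 20
  s2 <- s
  ix <- which(s2$atoms$resno == 5)
  s2$atoms$b[ix] <- c(10, 30, 10, 30, 20)[seq_along(ix)]
  expect_equal(bfactor_profile(s2, "A")$b_mean[5], 20)
  # planted high-b loop exceeds the flank mean
  s3 <- make_toy_structure(residues_per_chain = 15, seed = 2,
                           b_factors = setNames(rep(60, 4), 6:9))
  p3 <- bfactor_profile(s3, "A")
  expect_gt(mean(p3$b_mean[p3$resno %in% 6:9]), mean(p3$b_mean[!p3$resno %in% 6:9]))
  expect_error(bfactor_profile(s, "Z"), "unknown chain")
})

test_that("chain pairing by number and by sequence handles numbering offsets", {
  s <- make_toy_structure(residues_per_chain = 20, seed = 4)
  al <- pair_chains(s, "A", s, "A", mode = "by_number")
  expect_equal(nrow(al), 20)
  expect_equal(al$resno_a, al$resno_b)
  # renumbered copy: by_number finds nothing, by_sequence recovers full length
  hp <- make_homolog_pair(s, angle_deg = 30, axis = c(1, 1, 0),
                          translation = c(3, 0, 0), noise_sd = 0.1,
                          seed = 8, renumber_offset = 100)
  expect_error(pair_chains(hp$a, "A", hp$b, "A", mode = "by_number"), "zero")
  al2 <- pair_chains(hp$a, "A", hp$b, "A", mode = "by_sequence")
  expect_equal(nrow(al2), 20)
  expect_equal(al2$resno_b - al2$resno_a, rep(100, 20))
  xa <- as.matrix(hp$a$atoms[, c("x", "y", "z")])
  xb <- as.matrix(hp$b$atoms[, c("x", "y", "z")])
  expect_equal(superpose(xb, xa)$rmsd, hp$truth$rmsd, tolerance = 1e-9)
})
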