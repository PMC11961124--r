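make_jitter_traj <- function(n_frames, noise_sd, seed, core_size = 5,
                             motif_size = 5, tumbling = FALSE) {
  make_loop_trajectory(n_frames = n_frames, dt = 0.01, core_size = core_size,
                       motif_size = motif_size, transition_time = 0,
                       amplitudes = rep(0, motif_size), noise_sd = noise_sd,
                       seed = seed, tumbling = tumbling)
}

test_that("core superposition removes rigid tumbling", {
  tr <- make_jitter_traj(30, noise_sd = 0, seed = 5, tumbling = TRUE)
  al <- core_superpose(tr)
  # pure rigid motion: every frame collapses onto frame 1
  for (k in seq_along(al$frames))
    expect_lt(max(abs(al$frames[[k]] - al$frames[[1]])), 1e-8)
  # identity trajectory is unchanged
  tr0 <- make_jitter_traj(5, noise_sd = 0, seed = 5, tumbling = FALSE)
  al0 <- core_superpose(tr0)
  expect_equal(al0$frames[[3]], tr0$frames[[3]], tolerance = 1e-10)
  expect_error(core_superpose(tr, core_resno = 1), "fewer than 3")
})

test_that("per-residue RMSD series match construction and a brute-force oracle", {
  tr <- make_jitter_traj(10, noise_sd = 0, seed = 2)
  # displace residue 7 rigidly by 3 A in frame 4
  ix <- which(tr$topology$atoms$resno == 7)
  tr$frames[[4]][ix, 1] <- tr$frames[[4]][ix, 1] + 3
  ser <- residue_rmsd_series(tr, 6:8)
  expect_true(all(ser$values[1, ] == 0))  # reference row
  expect_equal(unname(ser$values[4, "7"]), 3.0, tolerance = 1e-9)
  expect_equal(unname(ser$values[4, "6"]), 0)

  jit <- make_jitter_traj(20, noise_sd = 0.5, seed = 3)
  ser2 <- residue_rmsd_series(jit, 3:6)
  for (k in c(5, 17)) for (r in 3:6) {
    ixr <- which(jit$topology$atoms$resno == r)
    oracle <- sqrt(mean(rowSums((jit$frames[[k]][ixr, , drop = FALSE] -
                                   jit$frames[[1]][ixr, , drop = FALSE])^2)))
    expect_equal(unname(ser2$values[k, as.character(r)]), oracle, tolerance = 1e-9)
  }
  expect_error(residue_rmsd_series(tr, 999), "not found")
})

test_that("pair-distance series track constructed separations", {
  tr <- make_jitter_traj(12, noise_sd = 0, seed = 4)
  d <- pair_distance_series(tr, "A:2:CA", "A:9:CA")
  expect_equal(length(unique(round(d, 9))), 1)  # static geometry
  # plant a linear separation ramp: CA of residue 9 walks away from its N
  ix <- which(tr$topology$atoms$resno == 9 & tr$topology$atoms$elety == "CA")
  ixn <- which(tr$topology$atoms$resno == 9 & tr$topology$atoms$elety == "N")
  npos <- tr$frames[[1]][ixn, ]
  for (k in seq_along(tr$frames))
    tr$frames[[k]][ix, ] <- npos + c(2 + 0.5 * (k - 1), 0, 0)
  d2 <- pair_distance_series(tr, "A:9:CA", "A:9:N")
  expect_equal(unname(d2), 2 + 0.5 * (seq_along(tr$frames) - 1),
               tolerance = 1e-12)
  # frame-by-frame oracle on a random trajectory
  jit2 <- make_jitter_traj(15, noise_sd = 0.4, seed = 19)
  d3 <- pair_distance_series(jit2, "A:2:CA", "A:8:CB")
  ia <- which(jit2$topology$atoms$resno == 2 & jit2$topology$atoms$elety == "CA")
  ib <- which(jit2$topology$atoms$resno == 8 & jit2$topology$atoms$elety == "CB")
  oracle <- vapply(jit2$frames, function(fr) sqrt(sum((fr[ia, ] - fr[ib, ])^2)),
                   numeric(1))
  expect_equal(unname(d3), oracle, tolerance = 1e-12)
})

test_that("RMSF matches the isotropic-jitter closed form and planted flexibility", {
  static <- make_jitter_traj(10, noise_sd = 0, seed = 6)
  expect_true(all(rmsf(static, 1:10) == 0))
  sigma <- 0.3
  jit <- make_jitter_traj(2000, noise_sd = sigma, seed = 7)
  rf <- rmsf(jit, 1:10)
  expect_equal(mean(rf), sigma * sqrt(3), tolerance = 0.05)
  # planted mobile motif exceeds the core
  amps <- rep(4, 6)
  tr <- make_loop_trajectory(n_frames = 120, dt = 0.1, core_size = 10,
                             motif_size = 6, transition_time = 5,
                             amplitudes = amps, noise_sd = 0.2, seed = 8,
                             tumbling = FALSE)
  rf2 <- rmsf(tr, 1:16)
  expect_gt(mean(rf2[as.character(11:16)]), 3 * mean(rf2[as.character(1:10)]))
  expect_error(rmsf(jit, 1:3, window = integer(0)), "empty")
})

test_that("transition detection finds planted concerted events and rejects flat series", {
  flat <- residue_rmsd_series(make_jitter_traj(80, noise_sd = 0.3, seed = 9), 1:10)
  cp0 <- detect_transitions(flat)
  expect_equal(nrow(cp0$events), 0)

  amps <- c(seq(3, 15, length.out = 18), 0, 0)
  tr <- make_loop_trajectory(n_frames = 200, dt = 0.1, core_size = 30,
                             motif_size = 20, transition_time = 6.0,
                             amplitudes = amps, noise_sd = 0.3, seed = 10)
  truth <- tr$topology$metadata$truth
  al <- core_superpose(tr, core_resno = truth$core_resno)
  ser <- residue_rmsd_series(al, truth$motif_resno)
  cp <- detect_transitions(ser)
  expect_equal(nrow(cp$events), 1)
  expect_equal(cp$events$time, 6.0, tolerance = 0.1)
  expect_true(cp$events$concerted)
  expect_equal(cp$events$n_residues, 18)

  expect_error(detect_transitions(ser, min_segment = 1), "at least 2")
})

test_that("staggered transitions give separate non-concerted events", {
  n_frames <- 160; dt <- 0.125
  times <- (seq_len(n_frames) - 1) * dt
  vals <- matrix(0.05, n_frames, 9)
  with_local_seed(11, {
    vals <- vals + matrix(abs(rnorm(length(vals), 0, 0.05)), n_frames, 9)
    for (j in 1:9) {
      t_step <- c(2, 8, 14)[ceiling(j / 3)]
      vals[times >= t_step, j] <- vals[times >= t_step, j] + 4
    }
  })
  ser <- structure(list(times = times, residues = 1:9, values = vals,
                        reference_frame = 1), class = "SeriesResult")
  cp <- detect_transitions(ser, concert_window = 1, concert_fraction = 0.75)
  expect_equal(nrow(cp$events), 3)
  expect_equal(cp$events$time, c(2, 8, 14), tolerance = 0.2)
  expect_false(any(cp$events$concerted))
})

test_that("block representatives are true medoids with the earliest-frame tie-break", {
  # window of jittered copies of one conformation
  jit <- make_jitter_traj(40, noise_sd = 0.2, seed = 12)
  blk <- block_representative(jit, c(0.1, 0.3))
  expect_true(blk$medoid_time >= 0.1 && blk$medoid_time <= 0.3)
  expect_lt(blk$mean_pairwise_rmsd, 0.2 * sqrt(6) * 1.5)

  # exhaustive independent re-implementation
  inw <- which(jit$times >= 0.1 & jit$times <= 0.3)
  rms <- function(i, j) {
    dd <- jit$frames[[i]] - jit$frames[[j]]
    sqrt(mean(rowSums(dd^2)))
  }
  sums <- vapply(inw, function(i) sum(vapply(inw, function(j) rms(i, j),
                                             numeric(1))), numeric(1))
  expect_equal(blk$medoid_frame, inw[which.min(sums)])

  # single-frame window and equal sub-clusters
  one <- block_representative(jit, c(0, 0))
  expect_equal(one$medoid_frame, 1)
  expect_equal(one$mean_pairwise_rmsd, 0)
  two_state <- make_jitter_traj(4, noise_sd = 0, seed = 13)
  two_state$frames[[3]] <- two_state$frames[[3]] + 5
  two_state$frames[[4]] <- two_state$frames[[4]] + 5
  tie <- block_representative(two_state, range(two_state$times))
  expect_equal(tie$medoid_frame, 1)  # equal sums -> earliest
  expect_error(block_representative(jit, c(100, 200)), "no frames")
})
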