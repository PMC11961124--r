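test_that("disulfide detection honors the distance cutoff and planted pairs", {
  s <- make_toy_structure(residues_per_chain = 20, seed = 1,
                          cys_placements = list(
                            list(chain = "A", resno = 4, partner = c("A", 6),
                                 distance = 2.05)))
  ss <- detect_disulfides(s)
  expect_equal(nrow(ss), 1)
  expect_equal(c(ss$resno_a, ss$resno_b), c(4, 6))
  expect_equal(ss$distance, 2.05, tolerance = 1e-6)
  # 2.6 A pair with cutoff 2.3 -> no bond
  s2 <- make_toy_structure(residues_per_chain = 20, seed = 1,
                           cys_placements = list(
                             list(chain = "A", resno = 4, partner = c("A", 6),
                                  distance = 2.6)))
  expect_equal(nrow(detect_disulfides(s2, bond_cutoff = 2.3)), 0)
  # no cysteines -> empty, not an error
  expect_equal(nrow(detect_disulfides(make_toy_structure(seed = 2))), 0)
})

test_that("greedy disulfide matching is symmetric, partner-unique and cutoff-faithful", {
  with_local_seed(31, {
    for (trial in 1:100) {
      n <- sample(4:10, 1)
      xyz <- matrix(runif(3 * n, 0, 12), ncol = 3)
      at <- data.frame(type = "ATOM", eleno = seq_len(n), elety = "SG", alt = "",
                       resid = "CYS", chain = "A", resno = seq_len(n) * 3,
                       insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       o = 1, b = 20, elesy = "S", solvent = FALSE)
      s <- new_structure("const", at)
      cutoff <- runif(1, 2, 6)
      ss <- detect_disulfides(s, bond_cutoff = cutoff)
      # every reported pair within cutoff
      if (nrow(ss) > 0) expect_true(all(ss$distance <= cutoff))
      # partner-unique
      ids <- c(ss$resno_a, ss$resno_b)
      expect_equal(anyDuplicated(ids), 0)
      # exhaustive-enumeration oracle: an unbonded SG may not have an
      # unbonded neighbor within the cutoff (greedy maximality)
      d <- as.matrix(dist(xyz)); diag(d) <- Inf
      free <- setdiff(seq_len(n) * 3, ids)
      if (length(free) >= 2) {
        fidx <- free / 3
        expect_true(all(d[fidx, fidx] > cutoff))
      }
    }
  })
})

test_that("the cysteine report partitions every cysteine into one class", {
  s <- make_toy_structure(residues_per_chain = 30, seed = 3,
                          cys_placements = list(
                            list(chain = "A", resno = 4, partner = c("A", 6),
                                 distance = 2.05),
                            list(chain = "A", resno = 12, partner = c("A", 14),
                                 distance = 4.0),
                            list(chain = "A", resno = 22, partner = c("A", 25),
                                 distance = 9.0),
                            list(chain = "A", resno = 29)))
  tab <- shrake_rupley(s, n_points = 480)
  rep_ <- cysteine_report(s, tab)
  sm <- rep_$summary
  expect_equal(sm$n_cysteines, 7)
  expect_equal(sm$n_disulfide + sm$n_exposed_free + sm$n_buried_free +
                 sm$n_unresolved, sm$n_cysteines)
  expect_equal(sm$n_disulfide, 2)
  expect_equal(sm$predicted_reactive, sm$n_exposed_free)
  cys <- rep_$cysteines
  # exchange tiers follow the constructed distances
  expect_equal(cys$exchange_tier[cys$resno == 12], "direct")
  expect_equal(cys$exchange_tier[cys$resno == 14], "direct")
  expect_equal(cys$exchange_tier[cys$resno == 22], "rearrangement")
  expect_equal(cys$nearest_thiol_distance[cys$resno == 12], 4.0, tolerance = 1e-6)
  # disulfide-bonded pair carries its partner
  expect_equal(cys$partner_resno[cys$resno == 4], 6)
})

test_that("a cysteine-free structure yields an empty report", {
  s <- make_toy_structure(residues_per_chain = 8, seed = 5)
  tab <- shrake_rupley(s, n_points = 480)
  rep_ <- cysteine_report(s, tab)
  expect_equal(rep_$summary$n_cysteines, 0)
  expect_equal(rep_$summary$predicted_reactive, 0)
})

test_that("DTNB stoichiometry is the stated ratio and exactly linear", {
  expect_equal(dtnb_stoichiometry(0.283, 1, 0.005, 14.15), 4.0)
  expect_equal(dtnb_stoichiometry(0, 1, 0.005), 0)
  with_local_seed(13, {
    for (k in 1:20) {
      A <- runif(1, 0, 2); l <- runif(1, 0.1, 2); c <- runif(1, 1e-4, 0.1)
      e <- runif(1, 5, 20)
      base <- dtnb_stoichiometry(A, l, c, e)
      expect_equal(dtnb_stoichiometry(2 * A, l, c, e), 2 * base)
      expect_equal(dtnb_stoichiometry(A, l, 2 * c, e), base / 2)
      expect_equal(dtnb_stoichiometry(A, 2 * l, c, e), base / 2)
    }
  })
  expect_error(dtnb_stoichiometry(0.3, 1, 0), "positive")
})

test_that("titration reconciliation applies the two-standard-deviation rule", {
  fake <- function(pred) structure(list(summary = list(predicted_reactive = pred)),
                                   class = "CysteineReport")
  expect_equal(reconcile_titration(fake(4), 4.0, 0.6)$verdict, "consistent")
  expect_equal(reconcile_titration(fake(8), 4.0, 0.6)$verdict, "inconsistent")
  expect_equal(reconcile_titration(fake(3), 4.0, 0.6)$verdict, "consistent")
  expect_error(reconcile_titration(fake(4), 4.0, -0.1), "non-negative")
})

test_that("specific activity follows the coupled-assay arithmetic", {
  expect_equal(specific_activity(0.0622, 6.22, 1, 1, 0.001), 10.0)
  expect_equal(specific_activity(0, assay_volume = 1, enzyme_mass = 1), 0)
  a1 <- specific_activity(0.05, assay_volume = 1, enzyme_mass = 0.002)
  a2 <- specific_activity(0.05, assay_volume = 1, enzyme_mass = 0.001)
  expect_equal(a2, 2 * a1)
  expect_warning(out <- specific_activity(-0.1, assay_volume = 1, enzyme_mass = 1),
                 "clipped")
  expect_equal(out, 0)
  expect_error(specific_activity(0.1, assay_volume = 1, enzyme_mass = 0), "positive")
})
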