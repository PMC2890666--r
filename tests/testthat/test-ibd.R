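test_that("sib IBD transition matrices follow the two-parent sharing chain", {
  expect_equal(sib_transition_matrix(0), diag(3), ignore_attr = TRUE)
  T5 <- sib_transition_matrix(0.5)
  for (k in 1:3) expect_equal(unname(T5[k, ]), c(0.25, 0.5, 0.25))
  T1 <- sib_transition_matrix(0.1)
  expect_equal(unname(T1["ibd2", "ibd2"]), (1 - 0.18)^2)  # psi = 2*.1*.9
  expect_equal(unname(T1["ibd2", "ibd2"]), 0.6724, tolerance = 1e-10)
  # rows sum to one; prior is stationary
  th <- c(0.01, 0.07, 0.23, 0.4)
  for (t in th) {
    Tm <- sib_transition_matrix(t)
    expect_equal(rowSums(Tm), rep(1, 3), ignore_attr = TRUE)
    expect_equal(as.vector(c(0.25, 0.5, 0.25) %*% Tm), c(0.25, 0.5, 0.25),
                 tolerance = 1e-12)
  }
  expect_error(sib_transition_matrix(0.6), "0, 0.5")
  expect_error(sib_transition_matrix(-0.1), "0, 0.5")
})

test_that("single-point emissions match population-frequency formulas", {
  freqs <- c(A = 0.5, B = 0.5)
  # both sibs missing: uninformative
  expect_equal(unname(singlepoint_emission(NULL, NULL, freqs = freqs)),
               c(1, 1, 1))
  # both A/A, untyped parents
  e <- singlepoint_emission(c("A", "A"), c("A", "A"), freqs = freqs)
  expect_equal(unname(e), c(0.0625, 0.125, 0.25), tolerance = 1e-12)
  # disjoint genotypes cannot share two alleles IBD
  e2 <- singlepoint_emission(c("A", "A"), c("B", "B"), freqs = freqs)
  expect_equal(unname(e2[["e2"]]), 0)
  expect_error(singlepoint_emission(c("A", "C"), c("A", "A"), freqs = freqs),
               "absent")
})

test_that("emissions agree with exhaustive transmission enumeration", {
  set.seed(6)
  freqs3 <- c(a = 0.5, b = 0.3, c = 0.2)
  draws <- function() sample(names(freqs3), 2, replace = TRUE, prob = freqs3)
  for (rep in 1:40) {
    gm <- draws(); gf <- draws()
    g1 <- c(gm[sample(1:2, 1)], gf[sample(1:2, 1)])
    g2 <- c(gm[sample(1:2, 1)], gf[sample(1:2, 1)])
    # vary information patterns: full, one parent, no parents, missing sib
    pat <- rep %% 4
    gm_in <- if (pat %in% c(0, 1)) gm else NULL
    gf_in <- if (pat %in% c(0, 2)) gf else NULL
    g1_in <- if (rep %% 7 == 0) NULL else g1
    e_or <- oracle_emission_configs(g1_in, g2, gm_in, gf_in, freqs3)
    e_pk <- singlepoint_emission(g1_in, g2, gm_in, gf_in, freqs3)
    expect_equal(unname(e_pk),
                 c(e_or[1], (e_or[2] + e_or[3]) / 2, e_or[4]),
                 tolerance = 1e-12)
  }
})

test_that("an uninformative single marker returns the sib-pair prior", {
  tr <- multipoint_pihat(matrix(1, 1, 3), marker_cm = 10)
  expect_equal(c(tr$p0, tr$p1, tr$p2), c(0.25, 0.5, 0.25))
  expect_equal(tr$pihat, 0.5)
})

test_that("tightly linked informative flanks dominate interior positions", {
  # both flanking markers say IBD 2 with near-zero recombination across
  e <- matrix(c(0, 0, 1,
                0, 0, 1), 2, 3, byrow = TRUE)
  tr <- multipoint_pihat(e, marker_cm = c(0, 0.002), grid_cm = 0.001)
  expect_gt(min(tr$p2), 0.9999)
})

test_that("multipoint posteriors equal brute-force path enumeration", {
  # printed 3-marker toy: asymmetric, parent-typed-style emissions
  e3 <- matrix(c(0.10, 0.30, 0.05, 0.55,
                 0.40, 0.10, 0.10, 0.40,
                 0.25, 0.25, 0.25, 0.25), 3, 4, byrow = TRUE)
  cm <- c(0, 7, 19)
  tr <- multipoint_pihat(e3, cm)
  or <- collapse_ibd(oracle_multipoint_posterior(e3, haldane_theta(diff(cm))))
  expect_lt(max(abs(as.matrix(tr[, c("p0", "p1", "p2")]) - or)), 1e-10)

  # random toys up to 5 markers, 3- and 4-column emission forms
  set.seed(8)
  for (m in 2:5) {
    e4 <- matrix(runif(m * 4, 0.01, 1), m, 4)
    cm <- sort(runif(m, 0, 40))
    tr4 <- multipoint_pihat(e4, cm)
    or4 <- collapse_ibd(oracle_multipoint_posterior(e4, haldane_theta(diff(cm))))
    expect_lt(max(abs(as.matrix(tr4[, c("p0", "p1", "p2")]) - or4)), 1e-10)
    # symmetric emissions given as 3 columns
    e3s <- matrix(runif(m * 3, 0.01, 1), m, 3)
    e4s <- cbind(e3s[, 1], e3s[, 2], e3s[, 2], e3s[, 3])
    tr3 <- multipoint_pihat(e3s, cm)
    or3 <- collapse_ibd(oracle_multipoint_posterior(e4s, haldane_theta(diff(cm))))
    expect_lt(max(abs(as.matrix(tr3[, c("p0", "p1", "p2")]) - or3)), 1e-10)
  }
})

test_that("posteriors are proper and invariant to reversing the map", {
  set.seed(9)
  m <- 5
  e4 <- matrix(runif(m * 4, 0.01, 1), m, 4)
  cm <- sort(runif(m, 0, 60))
  tr <- multipoint_pihat(e4, cm, grid_cm = seq(0, 60, by = 2))
  expect_equal(tr$p0 + tr$p1 + tr$p2, rep(1, nrow(tr)), tolerance = 1e-10)
  expect_true(all(tr$pihat >= 0 & tr$pihat <= 1))
  # reversal: flip positions and config order (mother/father order preserved,
  # marker order reversed)
  cm_rev <- max(cm) - rev(cm)
  tr_rev <- multipoint_pihat(e4[m:1, ], cm_rev, grid_cm = max(cm) - rev(seq(0, 60, by = 2)))
  expect_equal(rev(tr_rev$pihat), tr$pihat, tolerance = 1e-10)
  expect_equal(rev(tr_rev$p0), tr$p0, tolerance = 1e-10)
})

test_that("unordered maps and bad emission shapes are rejected", {
  expect_error(multipoint_pihat(matrix(1, 2, 3), c(10, 5)), "non-decreasing")
  expect_error(multipoint_pihat(matrix(1, 2, 5), c(5, 10)), "3 or 4 columns")
  expect_error(multipoint_pihat(matrix(1, 2, 3), c(5, 10, 15)), "match")
})

test_that("multipoint traces are calibrated against the simulated truth", {
  s <- small_sim(n_families = 120, seed = 19, len = 64)
  tr <- sib_ibd_traces(s$ped, s$map, grid_step = 4)
  at_m <- tr$traces[tr$traces$at_marker, ]
  truth <- s$truth$ibd
  cmn <- s$map$cm[match(colnames(truth), s$map$name)]
  pos_match <- match(round(at_m$pos_cm, 6), round(cmn, 6))
  k_true <- truth[cbind(match(at_m$pair_id, rownames(truth)), pos_match)]
  post_true <- as.matrix(at_m[, c("p0", "p1", "p2")])[cbind(seq_len(nrow(at_m)),
                                                            k_true + 1L)]
  prior <- c(0.25, 0.5, 0.25)[k_true + 1L]
  for (k in 0:2) {
    expect_gt(mean(post_true[k_true == k]), mean(prior[k_true == k]))
  }
  # posterior of the true state should beat the prior decisively on average
  expect_gt(mean(post_true - prior), 0.15)
  # and pihat should track true sharing
  expect_gt(cor(at_m$pihat, k_true / 2), 0.5)
})

test_that("null mean sharing is one half across pairs and positions", {
  s <- small_sim(n_families = 150, seed = 20, len = 96)
  tr <- sib_ibd_traces(s$ped, s$map, grid_step = 2)
  pair_means <- tapply(tr$traces$pihat, tr$traces$pair_id, mean)
  se <- sd(pair_means) / sqrt(length(pair_means))
  expect_lt(abs(mean(pair_means) - 0.5), 4 * se + 0.01)
})
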