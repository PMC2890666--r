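make_maps <- function() {
  str_map <- data.frame(name = c("S1", "S2", "S3"), chrom = 1,
                        cm = c(10, 25, 40), bp = NA)
  snp_map <- data.frame(name = sprintf("rs%02d", 1:9), chrom = 1,
                        cm = NA, bp = seq(5e6, 45e6, by = 5e6))
  list(str = str_map, snp = snp_map)
}

test_that("STRs are anchored by piecewise-linear cM-to-bp interpolation", {
  mm <- make_maps()
  anchors <- data.frame(chrom = 1, cm = c(0, 10, 20, 30, 50),
                        bp = c(0, 10e6, 20e6, 35e6, 60e6))
  cmap <- build_combined_map(mm$str, mm$snp, anchors = anchors)
  # at an anchor's cM exactly: that anchor's bp
  expect_equal(cmap$strs$mb[1], 10)
  # hand-computed piecewise values: 25 cM midway in [20,30] -> 27.5 Mb;
  # 40 cM midway in [30,50] -> 47.5 Mb
  expect_equal(cmap$strs$mb[2], 27.5)
  expect_equal(cmap$strs$mb[3], 47.5)
  expect_false(any(cmap$strs$extrapolated))
  # cM order is preserved in the anchored physical positions
  expect_true(all(diff(cmap$strs$mb) > 0))

  # midway between anchors at 10 and 20 Mb -> 15 Mb
  a2 <- data.frame(chrom = 1, cm = c(0, 20), bp = c(10e6, 20e6))
  cm2 <- build_combined_map(data.frame(name = "S", chrom = 1, cm = 10, bp = NA),
                            mm$snp, anchors = a2)
  expect_equal(cm2$strs$mb, 15)

  # outside the anchored range: extrapolated and flagged
  a3 <- data.frame(chrom = 1, cm = c(20, 30), bp = c(20e6, 30e6))
  cm3 <- build_combined_map(mm$str, mm$snp, anchors = a3)
  expect_true(cm3$strs$extrapolated[1])
  expect_equal(cm3$strs$mb[1], 10)   # linear extension of the terminal slope
})

test_that("linkage traces interpolate z along physical position", {
  mm <- make_maps()
  cmap <- build_combined_map(mm$str, mm$snp,
                             anchors = data.frame(chrom = 1, cm = c(0, 50),
                                                  bp = c(0, 50e6)))
  scan <- data.frame(factor = "PC1", chrom = 1,
                     pos_cm = c(10, 25, 40), p = c(0.00074, 0.5, 0.5))
  # SNP exactly at an STR's position takes the STR's z
  z <- linkage_trace_at_snps(scan, cmap)
  expect_equal(unname(z["rs02"]), qnorm(1 - 0.00074), tolerance = 1e-9)
  # midway between a linked and a null STR: average of the two z values
  mid <- (qnorm(1 - 0.00074) + 0) / 2
  snp_mid <- data.frame(name = "mid", chrom = 1, cm = NA, bp = 17.5e6)
  cmap2 <- build_combined_map(mm$str, snp_mid,
                              anchors = data.frame(chrom = 1, cm = c(0, 50),
                                                   bp = c(0, 50e6)))
  z2 <- linkage_trace_at_snps(scan, cmap2)
  expect_equal(unname(z2["mid"]), mid, tolerance = 1e-9)
  expect_equal(mid, 1.589, tolerance = 1e-3)
  # a flat p = 0.5 scan gives an all-zero trace
  scan0 <- transform(scan, p = 0.5)
  expect_equal(max(abs(linkage_trace_at_snps(scan0, cmap))), 0)
  # beyond the terminal STRs the trace holds the terminal value
  expect_equal(unname(z["rs09"]), 0)
  expect_equal(unname(z["rs01"]), unname(z["rs02"]))
})

test_that("weights are the normal CDF of z, normalized to mean one", {
  expect_equal(weights_from_trace(c(0, 0, 0)), rep(1, 3))
  w <- weights_from_trace(c(0, 1.6449))
  expect_equal(w, c(0.6897, 1.3103), tolerance = 1e-4)
  expect_equal(mean(w), 1, tolerance = 1e-12)
  # monotone in z
  z <- sort(rnorm(50))
  expect_true(all(diff(weights_from_trace(z)) > 0))
  expect_true(all(weights_from_trace(rnorm(50)) > 0))
  expect_error(weights_from_trace(c(0, Inf)), "finite")
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is one", {
  p <- c(0.001, 0.01, 0.02, 0.8, 0.9)
  st <- storey_qvalues(p, pi0 = 1)
  expect_equal(st$q, c(0.005, 0.025, 1 / 30, 0.9, 0.9), tolerance = 1e-12)
  expect_equal(st$q, oracle_bh(p), tolerance = 1e-12)
  # random fixtures
  set.seed(16)
  for (r in 1:10) {
    pr <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(storey_qvalues(pr, pi0 = 1)$q, oracle_bh(pr),
                 tolerance = 1e-12)
  }
})

test_that("Storey machinery estimates pi0 and orders q with p", {
  # pure null at the boundary
  st1 <- storey_qvalues(rep(1, 10))
  expect_equal(st1$pi0, 1)
  expect_equal(st1$q, rep(1, 10))
  # uniform null: pi0 near 1
  set.seed(17)
  p <- runif(5000)
  st <- storey_qvalues(p)
  expect_gt(st$pi0, 0.9)
  # q non-decreasing in p rank
  o <- order(p)
  expect_true(all(diff(st$q[o]) >= -1e-15))
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("region-specific Bonferroni screens +/- 5 Mb around linked STRs", {
  mm <- make_maps()
  cmap <- build_combined_map(mm$str, mm$snp,
                             anchors = data.frame(chrom = 1, cm = c(0, 50),
                                                  bp = c(0, 50e6)))
  scan <- data.frame(factor = "PC1", chrom = 1, pos_cm = c(10, 25, 40),
                     p = c(1e-4, 0.4, 2e-4))
  # S1 at 10 Mb and S3 at 40 Mb are linked; windows 5-15 and 35-45 Mb
  assoc <- data.frame(snp = cmap$snps$name, chrom = 1, bp = cmap$snps$bp,
                      p = c(0.04, 1e-3, 0.2, 0.5, 0.5, 0.5, 0.6, 0.05 / 3, 0.9))
  rb <- region_bonferroni(scan, assoc, cmap)
  expect_equal(nrow(rb$regions), 2L)
  expect_equal(rb$regions$n_snps, c(3L, 3L))       # 3 SNPs in each window
  expect_equal(rb$regions$threshold, c(0.05 / 3, 0.05 / 3))
  # rs02 (p=1e-3) clears 0.0167; rs08 sits exactly at the threshold: excluded
  expect_equal(rb$snps, "rs02")
  # overlapping windows deduplicate in the summary
  scan_all <- transform(scan, p = 1e-4)
  rb2 <- region_bonferroni(scan_all, assoc, cmap)
  expect_equal(anyDuplicated(rb2$snps), 0L)
})

test_that("unit weights make the prioritized report equal the unweighted analysis", {
  set.seed(18)
  mm <- make_maps()
  cmap <- build_combined_map(mm$str, mm$snp,
                             anchors = data.frame(chrom = 1, cm = c(0, 50),
                                                  bp = c(0, 50e6)))
  assoc <- data.frame(snp = cmap$snps$name, chrom = 1, bp = cmap$snps$bp,
                      beta = rnorm(9), p = runif(9))
  z0 <- setNames(rep(0, 9), assoc$snp)
  rep0 <- prioritize_report(assoc, z0, weights_from_trace(z0))
  st <- storey_qvalues(assoc$p)
  expect_equal(rep0$q[match(assoc$snp, rep0$snp)], st$q, tolerance = 1e-12)
  expect_equal(rep0$p_weighted[match(assoc$snp, rep0$snp)],
               pmax(assoc$p, .Machine$double.eps), tolerance = 1e-15)
  expect_equal(attr(rep0, "pi0"), st$pi0)
  # mismatched SNP sets error
  z_bad <- setNames(rep(0, 9), rev(assoc$snp))
  expect_error(prioritize_report(assoc, z_bad, weights_from_trace(z_bad)),
               "disagree")
  expect_error(prioritize_report(assoc, z0[-1], weights_from_trace(z0[-1])),
               "same SNP set")
})

test_that("a small-p SNP in a linkage trough can lose significance", {
  # one SNP with p just under the Bonferroni line but sitting where the
  # linkage trace is deeply negative (weight << 1)
  mm <- make_maps()
  cmap <- build_combined_map(mm$str, mm$snp,
                             anchors = data.frame(chrom = 1, cm = c(0, 50),
                                                  bp = c(0, 50e6)))
  set.seed(19)
  p <- runif(9, 0.2, 1)
  p[4] <- 8e-9                       # Bonferroni-significant alone
  z <- setNames(c(2, 2, 1, -6, -6, -6, 1, 2, 2), cmap$snps$name)
  assoc <- data.frame(snp = cmap$snps$name, chrom = 1, bp = cmap$snps$bp,
                      beta = 0, p = p)
  rep1 <- prioritize_report(assoc, z, weights_from_trace(z))
  row <- rep1[rep1$snp == "rs04", ]
  expect_true(row$sig_bonferroni)
  expect_lt(row$weight, 1)
  expect_false(row$sig_weighted_fdr)
})

test_that("informative weights concentrate discoveries where linkage is", {
  # planted alternatives under a linkage peak: weighted FDR discovers at
  # least as much as the strict Bonferroni rule, and FDR stays controlled
  set.seed(20)
  m <- 2000
  truth <- rep(FALSE, m); truth[1:60] <- TRUE
  z_assoc <- rnorm(m); z_assoc[truth] <- z_assoc[truth] + 4.5
  p <- pnorm(z_assoc, lower.tail = FALSE)
  z_link <- c(rep(2.5, 100), rep(-0.5, m - 100))   # peak over the signals
  w <- weights_from_trace(z_link)
  st <- storey_qvalues(pmin(p / w, 1))
  n_weighted <- sum(st$q <= 0.05)
  n_bonf <- sum(p < 1e-8)
  expect_gte(n_weighted, n_bonf)
  fdp <- sum(st$q <= 0.05 & !truth) / max(1, n_weighted)
  expect_lt(fdp, 0.15)
})
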