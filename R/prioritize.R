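#' @title Linkage-weighted prioritization of association signals
#' @description Anchors the sparse STR linkage panel onto the physical SNP
#'   map, interpolates a continuous linkage trace to every SNP, converts it
#'   through the standard normal cumulative distribution into mean-one
#'   weights, divides the association p-values by the weights, computes
#'   Storey q-values, and applies the region-specific Bonferroni screen
#'   around linked STRs.
#' @name prioritize
NULL

#' Anchor STRs onto the physical (SNP) map
#'
#' Assigns each STR a physical coordinate in Mb by piecewise-linear
#' interpolation of its genetic (cM) position between anchor markers that
#' carry both scales. STRs outside the anchored cM range are extrapolated
#' from the nearest interval and flagged.
#'
#' @param str_map `genetic_map` rows for the STR panel.
#' @param snp_map `genetic_map` rows for the SNP panel.
#' @param anchors optional data frame (chrom, cm, bp) of interpolation
#'   anchors; defaults to the SNP map when it carries cM positions, else to
#'   the STR map's own (cm, bp) pairs.
#' @return a `combined_map`: list with `strs` (name, chrom, cm, mb,
#'   extrapolated) and `snps` (name, chrom, bp, mb).
#' @export
build_combined_map <- function(str_map, snp_map, anchors = NULL) {
  if (is.null(anchors)) {
    src <- if (all(is.finite(snp_map$cm))) snp_map else str_map
    anchors <- data.frame(chrom = src$chrom, cm = src$cm, bp = src$bp)
  }
  strs <- data.frame(name = str_map$name, chrom = str_map$chrom,
                     cm = str_map$cm, mb = NA_real_, extrapolated = FALSE,
                     stringsAsFactors = FALSE)
  for (ch in unique(strs$chrom)) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    a <- a[order(a$cm), , drop = FALSE]
    sel <- which(strs$chrom == ch)
    if (nrow(a) == 0L) stop("no physical anchors on chromosome ", ch)
    if (nrow(a) == 1L) {
      strs$mb[sel] <- a$bp / 1e6
      strs$extrapolated[sel] <- strs$cm[sel] != a$cm
      next
    }
    # rule = 2 clamps; linear extrapolation from the terminal interval instead
    interp <- stats::approx(a$cm, a$bp, xout = strs$cm[sel], rule = 2,
                            ties = "ordered")$y
    lo <- strs$cm[sel] < min(a$cm); hi <- strs$cm[sel] > max(a$cm)
    if (any(lo)) {
      sl <- (a$bp[2L] - a$bp[1L]) / max(a$cm[2L] - a$cm[1L], 1e-12)
      interp[lo] <- a$bp[1L] + sl * (strs$cm[sel][lo] - a$cm[1L])
    }
    if (any(hi)) {
      nA <- nrow(a)
      sl <- (a$bp[nA] - a$bp[nA - 1L]) / max(a$cm[nA] - a$cm[nA - 1L], 1e-12)
      interp[hi] <- a$bp[nA] + sl * (strs$cm[sel][hi] - a$cm[nA])
    }
    strs$mb[sel] <- interp / 1e6
    strs$extrapolated[sel] <- lo | hi
  }
  snps <- data.frame(name = snp_map$name, chrom = snp_map$chrom,
                     bp = snp_map$bp, mb = snp_map$bp / 1e6,
                     stringsAsFactors = FALSE)
  structure(list(strs = strs, snps = snps), class = "combined_map")
}

#' Interpolate the linkage trace to every SNP
#'
#' Converts each STR's one-sided linkage p-value to `z = qnorm(1 - p)` and
#' linearly interpolates z along physical position to every SNP; SNPs beyond
#' the terminal STRs take the terminal value. Chromosomes without an STR get
#' a zero trace with a warning. P-values are floored at machine epsilon
#' before the quantile transform.
#'
#' @param scan a `linkage_scan` restricted to (or filtered by) one factor.
#' @param cmap a `combined_map`.
#' @param factor optional factor name to filter `scan` by.
#' @return named numeric vector of linkage z per SNP (names = SNP ids).
#' @export
linkage_trace_at_snps <- function(scan, cmap, factor = NULL) {
  if (!is.null(factor)) scan <- scan[scan$factor == factor, , drop = FALSE]
  if (length(unique(scan$factor)) > 1L) {
    stop("scan covers multiple factors; pass `factor`")
  }
  z <- stats::setNames(rep(0, nrow(cmap$snps)), cmap$snps$name)
  for (ch in unique(cmap$snps$chrom)) {
    s_sel <- cmap$strs$chrom == ch
    snp_sel <- cmap$snps$chrom == ch
    if (!any(s_sel)) {
      warning("no STRs on chromosome ", ch, "; linkage trace set to 0")
      next
    }
    sc <- scan[scan$chrom == ch, , drop = FALSE]
    idx <- vapply(cmap$strs$cm[s_sel], function(cm) {
      which.min(abs(sc$pos_cm - cm))
    }, 1L)
    pstr <- pmax(sc$p[idx], .Machine$double.eps)
    zstr <- stats::qnorm(pstr, lower.tail = FALSE)
    xb <- cmap$strs$mb[s_sel]
    if (sum(s_sel) == 1L) {
      z[snp_sel] <- zstr
    } else {
      z[snp_sel] <- stats::approx(xb, zstr, xout = cmap$snps$mb[snp_sel],
                                  rule = 2, ties = "ordered")$y
    }
  }
  z
}

#' Weights from a linkage trace
#'
#' Raw weight `u = Phi(z)` per SNP, normalized to mean 1 over the analyzed
#' set (required for weighted-FDR validity); weights are strictly positive
#' and a flat trace (`z = 0`) gives all-unit weights.
#'
#' @param z per-SNP linkage z values.
#' @return numeric weight vector, mean exactly 1.
#' @export
weights_from_trace <- function(z) {
  if (any(!is.finite(z))) stop("linkage z must be finite")
  u <- stats::pnorm(z)
  u / mean(u)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0 = #(p > lambda) / (m (1 - lambda))`
#' (capped at 1) at a single fixed `lambda` and converts p-values to
#' q-values: `q_(i) = pi0 * min_{j >= i} m p_(j) / j`. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg adjustment. Input p-values are clipped to
#' (0, 1] first (linkage-weighted p-values can exceed 1).
#'
#' @param p p-values (possibly weighted, i.e. divided by mean-one weights).
#' @param lambda tuning constant for the null-proportion estimate.
#' @param pi0 optionally override the estimate (e.g. `pi0 = 1`).
#' @return list: `q` (same order as `p`), `pi0`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0L) stop("empty p-value vector")
  p <- pmin(pmax(p, .Machine$double.eps), 1)
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    if (pi0 <= 0) pi0 <- 1 / m   # degenerate: all p tiny
  }
  o <- order(p)
  q_sorted <- pi0 * pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Region-specific Bonferroni screen around linked STRs
#'
#' For every STR whose linkage p-value is below the suggestive threshold, a
#' window of +/- `half_width_mb` around its anchored physical position is
#' examined and SNPs with raw association p strictly below `alpha / n`
#' (n = SNPs tested in the window) are reported per region.
#'
#' @param scan a single-factor `linkage_scan`.
#' @param assoc an `assoc_table`.
#' @param cmap a `combined_map`.
#' @param factor optional factor name to filter `scan` by.
#' @param linked_p threshold defining a linked STR (default 7.4e-4).
#' @param half_width_mb window half-width in Mb (default 5).
#' @param alpha family-wise rate within a region (default 0.05).
#' @return list: `regions` (str, chrom, mb, n_snps, threshold),
#'   `hits` (per-region significant SNPs), `snps` (deduplicated SNP ids).
#' @export
region_bonferroni <- function(scan, assoc, cmap, factor = NULL,
                              linked_p = 7.4e-4, half_width_mb = 5,
                              alpha = 0.05) {
  if (!is.null(factor)) scan <- scan[scan$factor == factor, , drop = FALSE]
  regions <- list(); hits <- list()
  for (i in seq_len(nrow(cmap$strs))) {
    ch <- cmap$strs$chrom[i]
    sc <- scan[scan$chrom == ch, , drop = FALSE]
    if (nrow(sc) == 0L) next
    pstr <- sc$p[which.min(abs(sc$pos_cm - cmap$strs$cm[i]))]
    if (!is.finite(pstr) || pstr >= linked_p) next
    mb0 <- cmap$strs$mb[i]
    in_win <- assoc$chrom == ch &
      assoc$bp / 1e6 >= mb0 - half_width_mb &
      assoc$bp / 1e6 <= mb0 + half_width_mb
    nwin <- sum(in_win)
    thr <- if (nwin > 0L) alpha / nwin else NA_real_
    regions[[length(regions) + 1L]] <- data.frame(
      str = cmap$strs$name[i], chrom = ch, mb = mb0, linkage_p = pstr,
      n_snps = nwin, threshold = thr, stringsAsFactors = FALSE)
    if (nwin > 0L) {
      sig <- assoc[in_win & assoc$p < thr, , drop = FALSE]
      if (nrow(sig) > 0L) {
        hits[[length(hits) + 1L]] <- cbind(str = cmap$strs$name[i],
                                           sig[, c("snp", "chrom", "bp", "p")])
      }
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(str = character(0), chrom = integer(0), mb = numeric(0),
               linkage_p = numeric(0), n_snps = integer(0),
               threshold = numeric(0))
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(str = character(0), snp = character(0), chrom = integer(0),
               bp = numeric(0), p = numeric(0))
  list(regions = regions, hits = hits, snps = unique(hits$snp))
}

#' Assemble the prioritized association report
#'
#' Per-SNP table of the raw p-value, interpolated linkage z, weight, weighted
#' p-value (`p / w`, capped at 1), Storey q-value, the strict unweighted
#' genome-wide Bonferroni flag (`p < bonferroni`), the weighted-FDR flag
#' (`q <= alpha`) and region-screen membership. With all-unit weights the
#' output reduces exactly to the unweighted Storey analysis.
#'
#' @param assoc an `assoc_table`.
#' @param z per-SNP linkage z (from [linkage_trace_at_snps()]).
#' @param weights per-SNP weights (from [weights_from_trace()]).
#' @param regions output of [region_bonferroni()] (optional).
#' @param alpha FDR level (default 0.05).
#' @param bonferroni strict genome-wide threshold (default 1e-8).
#' @param lambda passed to [storey_qvalues()].
#' @param annotation optional data frame with columns `snp` and annotation
#'   columns (e.g. nearest gene) left-joined onto the report.
#' @return a `prioritized_results` data frame, ordered by weighted p.
#' @export
prioritize_report <- function(assoc, z, weights, regions = NULL,
                              alpha = 0.05, bonferroni = 1e-8, lambda = 0.5,
                              annotation = NULL) {
  if (length(z) != nrow(assoc) || length(weights) != nrow(assoc)) {
    stop("assoc, z and weights must cover the same SNP set")
  }
  if (!is.null(names(z)) && !identical(names(z), assoc$snp)) {
    stop("SNP sets of assoc and the linkage trace disagree")
  }
  p_raw <- pmax(assoc$p, .Machine$double.eps)
  p_w <- pmin(p_raw / weights, 1)
  st <- storey_qvalues(p_w, lambda = lambda)
  out <- data.frame(
    snp = assoc$snp, chrom = assoc$chrom, bp = assoc$bp,
    beta = assoc$beta, p = assoc$p, linkage_z = unname(z),
    weight = weights, p_weighted = p_w, q = st$q,
    sig_bonferroni = assoc$p < bonferroni,
    sig_weighted_fdr = st$q <= alpha,
    stringsAsFactors = FALSE)
  out$in_region <- if (!is.null(regions)) out$snp %in% regions$snps else NA
  if (!is.null(annotation)) {
    out <- merge(out, annotation, by = "snp", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(out$p_weighted, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pi0") <- st$pi0
  class(out) <- c("prioritized_results", "data.frame")
  out
}

#' One-call prioritization of an association scan by linkage evidence
#'
#' Chains [linkage_trace_at_snps()], [weights_from_trace()],
#' [region_bonferroni()] and [prioritize_report()] for one factor.
#'
#' @inheritParams prioritize_report
#' @inheritParams region_bonferroni
#' @param scan single-factor `linkage_scan` (or pass `factor`).
#' @param cmap a `combined_map`.
#' @return a `prioritized_results` data frame (attribute `regions` holds the
#'   region screen).
#' @export
prioritize <- function(assoc, scan, cmap, factor = NULL, alpha = 0.05,
                       bonferroni = 1e-8, linked_p = 7.4e-4,
                       half_width_mb = 5, lambda = 0.5, annotation = NULL) {
  ord <- match(assoc$snp, cmap$snps$name)
  if (any(is.na(ord))) stop("assoc contains SNPs absent from the combined map")
  z_all <- linkage_trace_at_snps(scan, cmap, factor = factor)
  z <- z_all[assoc$snp]
  w <- weights_from_trace(z)
  regions <- region_bonferroni(scan, assoc, cmap, factor = factor,
                               linked_p = linked_p,
                               half_width_mb = half_width_mb, alpha = alpha)
  rep <- prioritize_report(assoc, z, w, regions, alpha = alpha,
                           bonferroni = bonferroni, lambda = lambda,
                           annotation = annotation)
  attr(rep, "regions") <- regions
  rep
}
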