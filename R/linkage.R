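#' @title Haseman-Elston regression genome scan
#' @description Regression of squared sib-pair trait differences on estimated
#'   IBD sharing, evaluated along the multipoint grid, with one-sided testing
#'   of the negative-slope (linkage) alternative and Lander-Kruglyak
#'   significance classification.
#' @name linkage
NULL

#' Squared sib-pair trait differences
#'
#' `Y = (X1 - X2)^2` for every full sib pair; pairs with a missing score are
#' dropped (count in attribute `n_dropped`).
#'
#' @param scores named numeric vector of one factor's scores, names
#'   `family:individual` (one column of `factor_model$scores`).
#' @param pairs sib-pair table from [sib_pairs()].
#' @return data frame pair_id, family_id, Y with attribute `n_dropped`.
#' @export
squared_differences <- function(scores, pairs) {
  x1 <- scores[key_of(pairs$family_id, pairs$id1)]
  x2 <- scores[key_of(pairs$family_id, pairs$id2)]
  ok <- !is.na(x1) & !is.na(x2)
  out <- data.frame(pair_id = pairs$pair_id[ok],
                    family_id = pairs$family_id[ok],
                    Y = (x1[ok] - x2[ok])^2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Haseman-Elston regression at one position
#'
#' Ordinary least squares of the squared trait difference on estimated mean
#' IBD sharing, with an intercept. Linkage reduces the squared difference, so
#' the test is one-sided against a negative slope:
#' `p = P(T_{n-2} <= t)`.
#'
#' @param Y per-pair squared differences.
#' @param pihat per-pair estimated mean IBD sharing at the position.
#' @return list: beta, se, t, p (one-sided), n. Positions without variation
#'   in `pihat` return `p = 1` with a warning.
#' @export
he_regression <- function(Y, pihat) {
  ok <- !is.na(Y) & !is.na(pihat)
  Y <- Y[ok]; pihat <- pihat[ok]
  n <- length(Y)
  if (n < 3L) stop("need at least 3 sib pairs")
  sxx <- sum((pihat - mean(pihat))^2)
  if (sxx < .Machine$double.eps) {
    warning("no variation in pihat at this position; p set to 1")
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = 1, n = n))
  }
  beta <- sum((pihat - mean(pihat)) * (Y - mean(Y))) / sxx
  alpha <- mean(Y) - beta * mean(pihat)
  rss <- sum((Y - alpha - beta * pihat)^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  t <- beta / se
  list(beta = beta, se = se, t = t, p = stats::pt(t, df = n - 2L), n = n)
}

#' Convert a LOD score to a pointwise one-sided p-value
#'
#' One-sided mixture convention for the Haseman-Elston/allele-sharing
#' setting: `p = 0.5 * P(chisq_1 > 2 ln(10) * LOD)`; LOD 0 maps to p 0.5.
#'
#' @param lod LOD score(s), >= 0.
#' @return pointwise p-value(s).
#' @export
p_from_lod <- function(lod) {
  if (any(lod < 0)) stop("LOD must be non-negative")
  0.5 * stats::pchisq(2 * log(10) * lod, df = 1L, lower.tail = FALSE)
}

#' Convert a pointwise one-sided p-value to a LOD score
#'
#' Exact inverse of [p_from_lod()] on `p <= 0.5` via the closed form
#' `LOD = qnorm(1 - p)^2 / (2 ln 10)`; p-values above 0.5 (evidence against
#' linkage under the one-sided convention) map to LOD 0.
#'
#' @param p p-value(s) in (0, 1].
#' @return LOD score(s), >= 0.
#' @export
lod_from_p <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  ifelse(p >= 0.5, 0,
         stats::qnorm(p, lower.tail = FALSE)^2 / (2 * log(10)))
}

#' Lander-Kruglyak significance classification
#'
#' @param p pointwise p-value(s).
#' @param suggestive,significant,highly_significant class thresholds (strict
#'   inequality; the genome-wide defaults are p < 7.4e-4, 2e-5 and 3e-7).
#' @return character vector in
#'   `{none, suggestive, significant, highly_significant}`.
#' @export
classify_signal <- function(p, suggestive = 7.4e-4, significant = 2e-5,
                            highly_significant = 3e-7) {
  out <- rep("none", length(p))
  out[p < suggestive] <- "suggestive"
  out[p < significant] <- "significant"
  out[p < highly_significant] <- "highly_significant"
  out
}

#' Haseman-Elston genome scan over all factors
#'
#' One [he_regression()] per evaluation position per factor, over the
#' multipoint IBD traces.
#'
#' @param scores matrix of factor scores (rows keyed `family:individual`).
#' @param traces an `ibd_traces` object from [sib_ibd_traces()].
#' @param suggestive,significant,highly_significant classification
#'   thresholds.
#' @return a `linkage_scan` data frame: factor, chrom, pos_cm, n_pairs, beta,
#'   se, t, p, lod, class.
#' @export
genome_scan <- function(scores, traces, suggestive = 7.4e-4,
                        significant = 2e-5, highly_significant = 3e-7) {
  pairs <- traces$pairs
  tr <- traces$traces
  pos_tab <- unique(tr[, c("chrom", "pos_cm")])
  pos_tab <- pos_tab[order(pos_tab$chrom, pos_tab$pos_cm), , drop = FALSE]
  # pihat matrix: pairs x positions, in a fixed pair order
  pair_ids <- pairs$pair_id
  pim <- matrix(NA_real_, length(pair_ids), nrow(pos_tab),
                dimnames = list(pair_ids, NULL))
  key <- paste(tr$chrom, tr$pos_cm)
  poskey <- paste(pos_tab$chrom, pos_tab$pos_cm)
  col <- match(key, poskey)
  pim[cbind(match(tr$pair_id, pair_ids), col)] <- tr$pihat
  out <- list()
  for (fac in colnames(scores)) {
    sq <- squared_differences(scores[, fac], pairs)
    rows <- match(sq$pair_id, pair_ids)
    for (j in seq_len(nrow(pos_tab))) {
      fit <- he_regression(sq$Y, pim[rows, j])
      out[[length(out) + 1L]] <- data.frame(
        factor = fac, chrom = pos_tab$chrom[j], pos_cm = pos_tab$pos_cm[j],
        n_pairs = fit$n, beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
        stringsAsFactors = FALSE)
    }
  }
  scan <- do.call(rbind, out)
  scan$lod <- ifelse(is.na(scan$beta) | scan$beta >= 0, 0, lod_from_p(scan$p))
  scan$class <- classify_signal(scan$p, suggestive, significant,
                                highly_significant)
  class(scan) <- c("linkage_scan", "data.frame")
  scan
}

#' Peak summary of a linkage scan
#'
#' All positions reaching at least suggestive evidence, plus the per-factor,
#' per-chromosome peak.
#'
#' @param scan a `linkage_scan`.
#' @param map optional `genetic_map` used to name the nearest marker.
#' @return data frame of suggestive-or-better positions (possibly empty).
#' @export
linkage_peaks <- function(scan, map = NULL) {
  hits <- scan[scan$class != "none", , drop = FALSE]
  if (nrow(hits) > 0L && !is.null(map)) {
    hits$nearest_marker <- vapply(seq_len(nrow(hits)), function(i) {
      sub <- map[map$chrom == hits$chrom[i], , drop = FALSE]
      sub$name[which.min(abs(sub$cm - hits$pos_cm[i]))]
    }, "")
  }
  hits[order(hits$p), , drop = FALSE]
}
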