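#' @title Family-clustered SNP association
#' @description Per-SNP association of factor scores under a linear model
#'   with additive genotype coding, a family random intercept (exchangeable
#'   within-family correlation) fitted by maximum likelihood, and a
#'   cluster-robust "empirical" sandwich variance with families as clusters.
#' @name assoc
NULL

#' Additive dosage coding of a biallelic SNP
#'
#' Dosage = count of the coded allele (0/1/2), missing genotypes propagated.
#' The coded allele defaults to the minor allele by founder-weighted
#' frequency in the analyzed stratum.
#'
#' @param ped a `pedigree_set`.
#' @param snp SNP name.
#' @param coded_allele optional allele label to count.
#' @return named integer-ish vector keyed `family:individual`, with attribute
#'   `coded_allele`.
#' @export
encode_additive <- function(ped, snp, coded_allele = NULL) {
  a1 <- ped$g1[, snp]; a2 <- ped$g2[, snp]
  alleles <- sort(unique(stats::na.omit(c(a1, a2))))
  if (length(alleles) > 2L) {
    stop("marker '", snp, "' has ", length(alleles), " alleles; additive coding needs a biallelic SNP")
  }
  if (is.null(coded_allele)) {
    if (length(alleles) < 2L) {
      coded_allele <- if (length(alleles)) alleles else NA_character_
    } else {
      freq <- founder_weighted_allele_freq(ped, snp)
      coded_allele <- names(freq)[which.min(freq)]
    }
  }
  dos <- (a1 == coded_allele) + (a2 == coded_allele)
  attr(dos, "coded_allele") <- coded_allele
  dos
}

#' Linear model with a family random intercept and sandwich variance
#'
#' Fits `y = mu + beta * dosage (+ covariates) + family intercept + residual`
#' by maximum likelihood, profiling the fixed effects and residual variance
#' and optimizing the family-to-residual variance ratio (closed-form
#' generalized least squares per family). The random intercept induces equal
#' correlation between all members of a family. Reports the model-based
#' standard error and the cluster-robust sandwich standard error with
#' families as clusters; the Wald test of `beta = 0` uses the sandwich
#' standard error against the standard normal. A family variance estimated at
#' the zero boundary is flagged (`boundary = TRUE`), where the fit reduces
#' exactly to ordinary least squares.
#'
#' @param y response vector (factor scores).
#' @param dosage additive SNP dosages.
#' @param family family identifiers (clusters).
#' @param covariates optional numeric matrix of extra fixed effects.
#' @return an `assoc_fit` list: beta, se_model, se_sandwich, z, p,
#'   sigma2_family, sigma2_resid, icc, loglik, n, n_families, boundary.
#' @export
fit_family_lme <- function(y, dosage, family, covariates = NULL) {
  ok <- !is.na(y) & !is.na(dosage) & !is.na(family)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  y <- y[ok]; dosage <- as.numeric(dosage[ok]); family <- family[ok]
  n <- length(y)
  if (length(unique(family)) < 2L) stop("need at least 2 families")
  if (stats::var(dosage) < .Machine$double.eps) {
    stop("dosage has no variance (monomorphic in the analyzed sample)")
  }
  X <- cbind(`(Intercept)` = 1, dosage = dosage, covariates)
  fam_rows <- split(seq_len(n), family)

  gls_parts <- function(rho) {
    p <- ncol(X)
    A <- matrix(0, p, p); cvec <- numeric(p); yy <- 0; logdet <- 0
    for (rows in fam_rows) {
      Xf <- X[rows, , drop = FALSE]; yf <- y[rows]; nf <- length(rows)
      shrink <- rho / (1 + nf * rho)
      sx <- colSums(Xf); sy <- sum(yf)
      A <- A + crossprod(Xf) - shrink * tcrossprod(sx)
      cvec <- cvec + crossprod(Xf, yf) - shrink * sx * sy
      yy <- yy + sum(yf^2) - shrink * sy^2
      logdet <- logdet + log1p(nf * rho)
    }
    beta <- solve(A, cvec)
    rss <- yy - sum(cvec * beta)
    sigma2 <- rss / n
    nll <- 0.5 * (n * log(sigma2) + logdet + n * (1 + log(2 * pi)))
    list(A = A, beta = as.vector(beta), sigma2 = sigma2, nll = nll)
  }
  nll_of <- function(log_rho) gls_parts(exp(log_rho))$nll
  opt <- stats::optimize(nll_of, interval = c(-12, 8), tol = 1e-9)
  rho <- exp(opt$minimum)
  at0 <- gls_parts(0)
  boundary <- at0$nll <= opt$objective + 1e-8
  if (boundary) rho <- 0
  fit <- gls_parts(rho)
  Ainv <- solve(fit$A)
  se_model <- sqrt(fit$sigma2 * diag(Ainv))[2L]
  # cluster-robust sandwich: (sum X'V-1 X)^-1 [sum X'V-1 r r' V-1 X] (...)^-1
  meat <- matrix(0, ncol(X), ncol(X))
  for (rows in fam_rows) {
    Xf <- X[rows, , drop = FALSE]
    rf <- y[rows] - Xf %*% fit$beta
    nf <- length(rows)
    shrink <- rho / (1 + nf * rho)
    u <- crossprod(Xf, rf) - shrink * colSums(Xf) * sum(rf)
    meat <- meat + tcrossprod(u)
  }
  Vs <- Ainv %*% meat %*% Ainv
  se_sand <- sqrt(diag(Vs))[2L]
  z <- fit$beta[2L] / se_sand
  structure(list(
    beta = fit$beta[2L], se_model = unname(se_model),
    se_sandwich = unname(se_sand), z = unname(z),
    p = 2 * stats::pnorm(-abs(z)),
    sigma2_family = rho * fit$sigma2, sigma2_resid = fit$sigma2,
    icc = rho / (1 + rho), loglik = -fit$nll,
    coefficients = stats::setNames(fit$beta, colnames(X)),
    n = n, n_families = length(fam_rows), boundary = boundary
  ), class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit: beta = %.4g, sandwich SE = %.4g, z = %.3f, p = %.3g; icc = %.3f%s>\n",
              x$beta, x$se_sandwich, x$z, x$p, x$icc,
              if (x$boundary) " (family variance at zero boundary)" else ""))
  invisible(x)
}

#' Family-clustered association scan over a SNP panel
#'
#' One [fit_family_lme()] per biallelic SNP with dosage variance; monomorphic
#' SNPs are skipped with a warning. Marker QC flags (low minor allele
#' frequency, Hardy-Weinberg failure) are carried on the records — flagged
#' SNPs are analyzed, not removed.
#'
#' @param y named response vector (factor scores keyed `family:individual`).
#' @param ped a `pedigree_set`.
#' @param map the matching `genetic_map`; SNP-class markers are analyzed.
#' @param qc optional output of [marker_qc_flags()].
#' @param covariates optional covariate matrix (rows keyed like `y`).
#' @return an `assoc_table` data frame: snp, chrom, bp, coded_allele, beta,
#'   se_model, se_sandwich, z, p, n, n_families, low_maf, hwe_fail.
#' @export
genome_assoc <- function(y, ped, map, qc = NULL, covariates = NULL) {
  snps <- map[map$class == "SNP", , drop = FALSE]
  if (nrow(snps) == 0L) stop("no SNP-class markers in map")
  keys <- rownames(ped$g1)
  yv <- y[keys]
  fam <- ped$individuals$family_id
  out <- list(); skipped <- character(0)
  for (j in seq_len(nrow(snps))) {
    snp <- snps$name[j]
    dos <- tryCatch(encode_additive(ped, snp), error = function(e) NULL)
    if (is.null(dos) || stats::var(dos, na.rm = TRUE) < .Machine$double.eps ||
        all(is.na(dos))) {
      skipped <- c(skipped, snp)
      next
    }
    fit <- fit_family_lme(yv, dos[keys], fam, covariates)
    out[[length(out) + 1L]] <- data.frame(
      snp = snp, chrom = snps$chrom[j], bp = snps$bp[j],
      coded_allele = attr(dos, "coded_allele"),
      beta = fit$beta, se_model = fit$se_model,
      se_sandwich = fit$se_sandwich, z = fit$z, p = fit$p,
      n = fit$n, n_families = fit$n_families,
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " monomorphic/empty SNP(s) skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
  }
  tab <- do.call(rbind, out)
  if (!is.null(qc)) {
    m <- match(tab$snp, qc$marker)
    tab$low_maf <- qc$low_maf[m]
    tab$hwe_fail <- qc$hwe_fail[m]
  } else {
    tab$low_maf <- NA; tab$hwe_fail <- NA
  }
  class(tab) <- c("assoc_table", "data.frame")
  tab
}
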