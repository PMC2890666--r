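#' @title Covariate adjustment, Z-scoring and varimax-rotated principal components
#' @description Builds the factor phenotypes analyzed by the linkage and
#'   association stages: ordinary-least-squares residualization on clinical
#'   covariates, Z-scoring, principal components of the correlation matrix
#'   with the eigenvalue-greater-than-one retention rule, orthogonal varimax
#'   rotation, regression factor scores and loading-threshold labels.
#' @name factors
NULL

#' Residualize phenotypes on covariates
#'
#' Each phenotype column is replaced by its residual from an ordinary
#' least-squares regression on the covariate set. Rows with any missing
#' covariate are dropped (count recorded in attribute `n_dropped`). For the
#' `post_adjusted_for_pre` group, each post-treatment phenotype additionally
#' gets its matching pre-treatment phenotype in the design, so the residual
#' represents the treatment response. Phenotypes listed in
#' `extra_covariates` (e.g. shear-dependent platelet-function tests that
#' require von Willebrand factor) get the named extra covariate columns
#' appended to their design.
#'
#' @param tab data frame holding `family_id`, `individual_id`, covariate and
#'   phenotype columns (as produced by [simulate_phenotypes()]).
#' @param covariates character vector of covariate column names.
#' @param group one of `"pre"`, `"post"`, `"post_adjusted_for_pre"`; selects
#'   phenotype columns by their `pre_`/`post_` prefix and the adjustment rule.
#' @param extra_covariates named list: phenotype base name -> character vector
#'   of additional covariate columns for that phenotype only.
#' @return data frame of ids plus residual columns named by phenotype base
#'   name, with attribute `n_dropped`.
#' @export
adjust_covariates <- function(tab,
                              covariates = c("age", "sex", "bmi", "smoking"),
                              group = c("pre", "post", "post_adjusted_for_pre"),
                              extra_covariates = list()) {
  group <- match.arg(group)
  prefix <- if (group == "pre") "pre_" else "post_"
  pheno_cols <- grep(paste0("^", prefix), names(tab), value = TRUE)
  if (length(pheno_cols) == 0L) stop("no '", prefix, "*' phenotype columns found")
  missing_cov <- setdiff(covariates, names(tab))
  if (length(missing_cov) > 0L) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  keep <- stats::complete.cases(tab[, covariates, drop = FALSE])
  n_dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  out <- tab[, c("family_id", "individual_id"), drop = FALSE]
  for (pc in pheno_cols) {
    base <- sub(paste0("^", prefix), "", pc)
    design_cols <- covariates
    if (base %in% names(extra_covariates)) {
      design_cols <- c(design_cols, extra_covariates[[base]])
    }
    if (group == "post_adjusted_for_pre") {
      pre_col <- paste0("pre_", base)
      if (!pre_col %in% names(tab)) {
        stop("no matching pre-treatment column '", pre_col, "' for '", pc, "'")
      }
      design_cols <- c(design_cols, pre_col)
    }
    X <- cbind(`(Intercept)` = 1, as.matrix(tab[, design_cols, drop = FALSE]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("rank-deficient adjustment design for '", pc, "'; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    y <- tab[[pc]]
    ok <- !is.na(y)
    res <- rep(NA_real_, length(y))
    res[ok] <- qr.resid(qr(X[ok, , drop = FALSE]), y[ok])
    out[[base]] <- res
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "group") <- group
  out
}

#' Z-score phenotype columns
#'
#' Centers each numeric column to mean 0 and scales to sample standard
#' deviation 1 (n-1 convention). Identifier columns `family_id` and
#' `individual_id` are passed through.
#'
#' @param tab data frame (or matrix) of residualized phenotypes.
#' @return object of the same shape with standardized columns.
#' @export
zscore <- function(tab) {
  id_cols <- intersect(c("family_id", "individual_id"), colnames(tab))
  num_cols <- setdiff(colnames(tab), id_cols)
  for (cc in num_cols) {
    x <- tab[[cc]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      stop("column '", cc, "' has zero variance; cannot Z-score")
    }
    tab[[cc]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  tab
}

#' The varimax criterion of a loading matrix
#'
#' Sum over factors of the variance of squared loadings — the objective that
#' orthogonal varimax rotation maximizes (computed on raw, unnormalized
#' loadings).
#'
#' @param loadings numeric matrix, phenotypes x factors.
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- loadings^2
  sum(apply(L2, 2L, function(col) mean((col - mean(col))^2)))
}

#' Principal components with varimax rotation
#'
#' Eigendecomposition of the phenotype correlation matrix; components with
#' eigenvalue above `eigen_min` (default 1, the Kaiser rule) are retained and
#' their loading matrix is varimax-rotated (Kaiser row normalization on by
#' default). Factor scores use the regression method on the rotated loadings.
#' Components are ordered by variance explained after rotation, with the sign
#' of each fixed so its largest-magnitude loading is positive.
#'
#' @param Z data frame or matrix of Z-scored phenotypes (ids passed through
#'   to score row names when present).
#' @param eigen_min retention threshold on unrotated eigenvalues.
#' @param kaiser logical; apply Kaiser row normalization inside the rotation.
#' @param tol convergence tolerance of the rotation criterion.
#' @param group label stored on the model (`pre`, `post`,
#'   `post_adjusted_for_pre`, ...).
#' @param loading_cutoff threshold for component labels.
#' @return a `factor_model`: rotated `loadings`, all unrotated `eigenvalues`,
#'   orthogonal `rotation` matrix, per-individual `scores`, per-component
#'   `labels`, `retained` count and `group`.
#' @export
pca_varimax <- function(Z, eigen_min = 1, kaiser = TRUE, tol = 1e-8,
                        group = "pre", loading_cutoff = 0.4) {
  id_cols <- intersect(c("family_id", "individual_id"), colnames(Z))
  keys <- if (length(id_cols) == 2L) key_of(Z$family_id, Z$individual_id) else
    rownames(Z)
  X <- as.matrix(Z[, setdiff(colnames(Z), id_cols), drop = FALSE])
  storage.mode(X) <- "double"
  if (ncol(X) < 2L) stop("need at least two phenotypes")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (length(keys) > 0L) keys <- keys[stats::complete.cases(
    as.matrix(Z[, setdiff(colnames(Z), id_cols), drop = FALSE]))]
  if (nrow(X) <= ncol(X)) stop("need more individuals than phenotypes")
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  retain <- which(eig$values > eigen_min)
  if (length(retain) == 0L) stop("no components retained (no eigenvalue > ",
                                 eigen_min, ")")
  k <- max(retain)
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(L) <- colnames(X)
  if (k >= 2L) {
    vm <- stats::varimax(L, normalize = kaiser, eps = tol)
    rot <- vm$rotmat
    Lr <- L %*% rot
  } else {
    rot <- matrix(1, 1L, 1L)
    Lr <- L
  }
  # order by post-rotation variance explained; fix signs
  ord <- order(colSums(Lr^2), decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  sgn <- apply(Lr, 2L, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  Lr <- sweep(Lr, 2L, sgn, `*`)
  rot <- sweep(rot, 2L, sgn, `*`)
  colnames(Lr) <- sprintf("PC%d", seq_len(k))
  # regression-method scores on the rotated loadings
  Zs <- scale(X)
  S <- Zs %*% solve(R, Lr)
  S <- sweep(S, 2L, colMeans(S))
  rownames(S) <- keys
  colnames(S) <- colnames(Lr)
  fm <- structure(
    list(loadings = Lr, eigenvalues = eig$values, rotation = rot,
         scores = S, retained = k, group = group, labels = NULL),
    class = "factor_model")
  fm$labels <- label_components(fm, cutoff = loading_cutoff)
  fm
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model '%s': %d of %d components retained (eigenvalue > 1)>\n",
              x$group, x$retained, length(x$eigenvalues)))
  for (j in seq_len(x$retained)) {
    lab <- x$labels[[j]]
    cat(sprintf("  %s: %s\n", colnames(x$loadings)[j],
                if (length(lab)) paste(lab, collapse = ", ") else "(no loading above cutoff)"))
  }
  invisible(x)
}

#' Label components by their primary phenotypes
#'
#' Each component is labeled by the phenotypes whose absolute rotated loading
#' exceeds the cutoff (default 0.4), ordered by decreasing absolute loading.
#' Empty label sets are allowed.
#'
#' @param fm a `factor_model`.
#' @param cutoff absolute-loading threshold (strict inequality).
#' @return list (one character vector per retained component).
#' @export
label_components <- function(fm, cutoff = 0.4) {
  lapply(seq_len(ncol(fm$loadings)), function(j) {
    l <- fm$loadings[, j]
    sel <- which(abs(l) > cutoff)
    names(sort(abs(l[sel]), decreasing = TRUE))
  })
}
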