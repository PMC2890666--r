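#' @title Gene-drop simulator of family marker and phenotype data
#' @description Generates nuclear families ascertained for two or more
#'   siblings, a sparse multiallelic STR panel plus a dense biallelic SNP
#'   panel dropped through the pedigree on a Haldane map, a QTL contributing a
#'   configured fraction of variance to latent "response" factors, polygenic
#'   and shared-family variance, covariates, and pre/post/response phenotype
#'   triplets — together with a truth record (true IBD, true QTL dosages, true
#'   factor values) used as the oracle in validation.
#' @name simgen
NULL

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' assuming no crossover interference: `theta = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cm genetic distance in centimorgans (vectorized, must be >= 0).
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_theta <- function(d_cm) {
  if (any(d_cm < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Simulation configuration
#'
#' Defaults mirror the study design this package validates against: nuclear
#' families with two typed parents and two or more siblings, two population
#' strata with stratum-specific allele frequencies analyzed separately, an STR
#' panel at 8 cM average spacing plus a dense SNP panel, and a QTL acting on
#' one latent aspirin-response factor.
#'
#' @param n_families families per stratum.
#' @param sibs_per_family integer, or integer vector of sibship sizes sampled
#'   uniformly per family.
#' @param n_strata number of population strata.
#' @param chromosomes data frame with columns `length_cm` and `length_mb`.
#' @param str_spacing_cm STR panel spacing in cM.
#' @param snp_spacing_kb SNP panel spacing in kb; `0` omits the SNP panel.
#' @param str_alleles range (min, max) of STR allele counts.
#' @param snp_maf_range SNP minor-allele-frequency range (uniform draw).
#' @param qtl either a single list `(chrom, cm, h2, maf, factor)` applied to
#'   every stratum, a list of such lists (one per stratum), or `NULL` for no
#'   QTL. The QTL is realized as a member of the SNP panel (closest panel SNP
#'   to the requested position) when a SNP panel exists, otherwise as a latent
#'   biallelic locus.
#' @param polygenic_h2 fraction of latent-factor variance from a polygenic
#'   component with kinship-proportional covariance.
#' @param family_env fraction of latent-factor variance shared by all members
#'   of a family.
#' @param n_raw_phenotypes number of observed phenotypes per visit.
#' @param factor_loadings raw-phenotype x latent-factor loading matrix;
#'   default is a 3-block structure (loading 0.8) over the phenotypes.
#' @param covariate_effects named list of per-unit covariate effects applied
#'   to every raw phenotype (`age`, `sex`, `bmi`, `smoking`); `vwf` applies
#'   only to the phenotypes in `vwf_phenos`.
#' @param vwf_phenos indices of phenotypes (the PFA-like ones) that carry the
#'   von-Willebrand-factor covariate effect.
#' @param missing_rate marker genotype missingness rate.
#' @param seed optional integer seed applied at the start of [gene_drop()].
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_families = 250L,
                       sibs_per_family = 2L,
                       n_strata = 2L,
                       chromosomes = data.frame(length_cm = c(120, 120),
                                                length_mb = c(120, 120)),
                       str_spacing_cm = 8,
                       snp_spacing_kb = 500,
                       str_alleles = c(4L, 8L),
                       snp_maf_range = c(0.05, 0.5),
                       qtl = list(chrom = 1L, cm = 50, h2 = 0.3,
                                  maf = 0.3, factor = 1L),
                       polygenic_h2 = 0.2,
                       family_env = 0.1,
                       n_raw_phenotypes = 12L,
                       factor_loadings = NULL,
                       covariate_effects = list(age = 0.01, sex = 0.2,
                                                bmi = 0.02, smoking = 0.3,
                                                vwf = 0.01),
                       vwf_phenos = 1L,
                       missing_rate = 0.0035,
                       seed = NULL) {
  if (str_spacing_cm <= 0) stop("str_spacing_cm must be positive")
  if (snp_spacing_kb < 0) stop("snp_spacing_kb must be non-negative")
  if (is.null(factor_loadings)) {
    n_factors <- 3L
    factor_loadings <- matrix(0, n_raw_phenotypes, n_factors)
    block <- rep(seq_len(n_factors), length.out = n_raw_phenotypes)
    block <- sort(block)
    factor_loadings[cbind(seq_len(n_raw_phenotypes), block)] <- 0.8
  }
  if (nrow(factor_loadings) != n_raw_phenotypes) {
    stop("factor_loadings must have n_raw_phenotypes rows")
  }
  if (any(rowSums(factor_loadings^2) > 1)) {
    stop("phenotype communalities (row sums of squared loadings) must be <= 1")
  }
  if (!is.null(qtl) && !is.null(qtl$chrom)) qtl <- rep(list(qtl), n_strata)
  h2q <- if (is.null(qtl)) 0 else max(vapply(qtl, function(q) q$h2, 0))
  if (h2q + polygenic_h2 + family_env > 1) {
    stop("h2_qtl + polygenic_h2 + family_env must be <= 1")
  }
  cfg <- list(n_families = as.integer(n_families),
              sibs_per_family = as.integer(sibs_per_family),
              n_strata = as.integer(n_strata),
              chromosomes = chromosomes,
              str_spacing_cm = str_spacing_cm,
              snp_spacing_kb = snp_spacing_kb,
              str_alleles = str_alleles,
              snp_maf_range = snp_maf_range,
              qtl = qtl,
              polygenic_h2 = polygenic_h2,
              family_env = family_env,
              n_raw_phenotypes = as.integer(n_raw_phenotypes),
              factor_loadings = factor_loadings,
              covariate_effects = covariate_effects,
              vwf_phenos = vwf_phenos,
              missing_rate = missing_rate,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# marker panel layout for one stratum: STRs mid-spaced, SNPs on a kb grid,
# cM and bp tied by the per-chromosome linear cM/Mb ratio
build_sim_map <- function(cfg, stratum) {
  maps <- list()
  for (ch in seq_len(nrow(cfg$chromosomes))) {
    len_cm <- cfg$chromosomes$length_cm[ch]
    len_mb <- cfg$chromosomes$length_mb[ch]
    ratio <- len_cm / len_mb              # cM per Mb
    str_cm <- seq(cfg$str_spacing_cm / 2, len_cm, by = cfg$str_spacing_cm)
    strs <- data.frame(
      name = sprintf("D%dS%03d", ch, seq_along(str_cm)),
      chrom = ch, cm = str_cm, bp = round(str_cm / ratio * 1e6),
      class = "STR", stringsAsFactors = FALSE)
    snps <- NULL
    if (cfg$snp_spacing_kb > 0) {
      snp_bp <- seq(cfg$snp_spacing_kb * 500, len_mb * 1e6,
                    by = cfg$snp_spacing_kb * 1000)
      snps <- data.frame(
        name = sprintf("rs%d_%05d", ch, seq_along(snp_bp)),
        chrom = ch, cm = snp_bp / 1e6 * ratio, bp = snp_bp,
        class = "SNP", stringsAsFactors = FALSE)
    }
    maps[[ch]] <- rbind(strs, snps)
  }
  map <- do.call(rbind, maps)
  map <- map[order(map$chrom, map$cm, map$bp), , drop = FALSE]
  rownames(map) <- NULL
  # stratum-specific allele frequencies: STR Dirichlet(1), SNP uniform MAF
  map$alleles <- vector("list", nrow(map))
  map$freqs <- vector("list", nrow(map))
  for (j in seq_len(nrow(map))) {
    if (map$class[j] == "STR") {
      k <- sample(seq(cfg$str_alleles[1], cfg$str_alleles[2]), 1L)
      f <- stats::rgamma(k, 1); f <- f / sum(f)
      map$alleles[[j]] <- as.character(seq_len(k))
    } else {
      maf <- stats::runif(1, cfg$snp_maf_range[1], cfg$snp_maf_range[2])
      f <- c(1 - maf, maf)
      map$alleles[[j]] <- c("A", "B")
    }
    map$freqs[[j]] <- stats::setNames(f, map$alleles[[j]])
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Drop founder haplotypes through simulated nuclear families
#'
#' Founder haplotypes are drawn from stratum-specific allele frequencies;
#' offspring gametes are formed by a two-state Markov recombination process
#' along the Haldane map (no interference). True IBD sharing for every full
#' sib pair is recorded at every marker, and generated genotypes are
#' Mendelian-consistent by construction (before optional missingness
#' injection).
#'
#' @param cfg a [sim_config()].
#' @return a `gene_drop` object: list of per-stratum lists with components
#'   `ped` (pedigree_set), `map` (genetic_map with true `freqs`), and `truth`
#'   (pairs, `ibd` matrix pairs x markers, per-individual QTL dosage, the QTL
#'   locus), plus the `config`.
#' @export
gene_drop <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  strata <- lapply(seq_len(cfg$n_strata), function(s) {
    drop_one_stratum(cfg, s)
  })
  names(strata) <- sprintf("stratum%d", seq_len(cfg$n_strata))
  structure(list(strata = strata, config = cfg), class = "gene_drop")
}

drop_one_stratum <- function(cfg, stratum) {
  map <- build_sim_map(cfg, stratum)
  qtl <- if (is.null(cfg$qtl)) NULL else cfg$qtl[[stratum]]
  qtl_name <- NULL
  if (!is.null(qtl)) {
    cand <- which(map$chrom == qtl$chrom & map$class == "SNP")
    if (length(cand) > 0L) {
      # causal variant is a member of the dense panel
      j <- cand[which.min(abs(map$cm[cand] - qtl$cm))]
      map$freqs[[j]] <- stats::setNames(c(1 - qtl$maf, qtl$maf), c("A", "B"))
      qtl_name <- map$name[j]
    } else {
      # no SNP panel: insert a latent biallelic locus (class QTL) dropped
      # through the pedigree but excluded from IBD, QC and association
      ratio <- cfg$chromosomes$length_cm[qtl$chrom] /
        cfg$chromosomes$length_mb[qtl$chrom]
      row <- data.frame(name = sprintf("QTL%d", qtl$chrom),
                        chrom = qtl$chrom, cm = qtl$cm,
                        bp = round(qtl$cm / ratio * 1e6), class = "QTL",
                        stringsAsFactors = FALSE)
      row$alleles <- list(c("A", "B"))
      row$freqs <- list(stats::setNames(c(1 - qtl$maf, qtl$maf), c("A", "B")))
      map <- rbind(map, row)
      map <- map[order(map$chrom, map$cm, map$bp), , drop = FALSE]
      rownames(map) <- NULL
      class(map) <- c("genetic_map", "data.frame")
      qtl_name <- row$name
    }
  }
  sizes <- if (length(cfg$sibs_per_family) == 1L) {
    rep(cfg$sibs_per_family, cfg$n_families)
  } else {
    sample(cfg$sibs_per_family, cfg$n_families, replace = TRUE)
  }
  fam_ids <- sprintf("F%s%04d", stratum, seq_len(cfg$n_families))
  m <- nrow(map)
  chrom_idx <- split(seq_len(m), map$chrom)
  theta <- lapply(chrom_idx, function(ix) haldane_theta(diff(map$cm[ix])))

  ind_list <- list(); g1_list <- list(); g2_list <- list()
  pair_list <- list(); ibd_list <- list()
  draw_haplo <- function() {
    vapply(map$freqs, function(f) sample(names(f), 1L, prob = f), "")
  }
  inherit_vec <- function() {
    # per-chromosome two-state Markov chain over marker indices
    out <- integer(m)
    for (ci in seq_along(chrom_idx)) {
      ix <- chrom_idx[[ci]]
      flips <- stats::runif(length(ix) - 1L) < theta[[ci]]
      out[ix] <- 1L + (cumsum(c(sample(0:1, 1L), flips)) %% 2L)
    }
    out
  }
  for (f in seq_len(cfg$n_families)) {
    fam <- fam_ids[f]; k <- sizes[f]
    fa <- cbind(draw_haplo(), draw_haplo())
    mo <- cbind(draw_haplo(), draw_haplo())
    ids <- c("01", "02", sprintf("%02d", 2L + seq_len(k)))
    ind_list[[f]] <- data.frame(
      family_id = fam, individual_id = ids,
      father_id = c(MISSING_CODE, MISSING_CODE, rep("01", k)),
      mother_id = c(MISSING_CODE, MISSING_CODE, rep("02", k)),
      sex = c(1L, 2L, sample(1:2, k, replace = TRUE)),
      stringsAsFactors = FALSE)
    ivf <- matrix(0L, k, m); ivm <- matrix(0L, k, m)
    cg1 <- matrix("", k + 2L, m); cg2 <- matrix("", k + 2L, m)
    cg1[1L, ] <- fa[, 1L]; cg2[1L, ] <- fa[, 2L]
    cg1[2L, ] <- mo[, 1L]; cg2[2L, ] <- mo[, 2L]
    for (c_i in seq_len(k)) {
      ivf[c_i, ] <- inherit_vec(); ivm[c_i, ] <- inherit_vec()
      cg1[2L + c_i, ] <- fa[cbind(seq_len(m), ivf[c_i, ])]
      cg2[2L + c_i, ] <- mo[cbind(seq_len(m), ivm[c_i, ])]
    }
    g1_list[[f]] <- cg1; g2_list[[f]] <- cg2
    if (k >= 2L) {
      cmb <- utils::combn(k, 2L)
      for (p_i in seq_len(ncol(cmb))) {
        a <- cmb[1L, p_i]; b <- cmb[2L, p_i]
        pair_list[[length(pair_list) + 1L]] <- data.frame(
          family_id = fam, id1 = ids[2L + a], id2 = ids[2L + b],
          stringsAsFactors = FALSE)
        ibd_list[[length(ibd_list) + 1L]] <-
          (ivf[a, ] == ivf[b, ]) + (ivm[a, ] == ivm[b, ])
      }
    }
  }
  individuals <- do.call(rbind, ind_list)
  g1 <- do.call(rbind, g1_list); g2 <- do.call(rbind, g2_list)
  colnames(g1) <- colnames(g2) <- map$name
  rownames(g1) <- rownames(g2) <- key_of(individuals$family_id,
                                         individuals$individual_id)
  qtl_dosage <- NULL
  if (!is.null(qtl_name)) {
    ref <- map$alleles[[match(qtl_name, map$name)]]
    eff <- ref[length(ref)]                  # "B" for SNPs
    qtl_dosage <- (g1[, qtl_name] == eff) + (g2[, qtl_name] == eff)
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(g1)) < cfg$missing_rate,
                   nrow(g1), ncol(g1))
    g1[miss] <- NA_character_; g2[miss] <- NA_character_
  }
  ped <- new_pedigree_set(individuals, g1, g2,
                          sprintf("stratum%d", stratum))
  pairs <- do.call(rbind, pair_list)
  pairs <- cbind(pair_id = paste(pairs$family_id, pairs$id1, pairs$id2,
                                 sep = ":"), pairs)
  ibd <- do.call(rbind, ibd_list)
  rownames(ibd) <- pairs$pair_id
  colnames(ibd) <- map$name
  truth <- list(pairs = pairs, ibd = ibd, qtl_dosage = qtl_dosage,
                qtl = qtl, qtl_marker = qtl_name)
  list(ped = ped, map = map, truth = truth)
}

#' @export
print.gene_drop <- function(x, ...) {
  cat(sprintf("<gene_drop: %d strata x %d families, %d markers>\n",
              length(x$strata), x$config$n_families,
              nrow(x$strata[[1]]$map)))
  invisible(x)
}

#' Simulate factor-structured phenotypes and covariates for one stratum
#'
#' Latent factors are built as `sqrt(h2_qtl) * standardized QTL dosage`
#' (response factors only, on the configured factor) plus a polygenic
#' component with kinship-proportional covariance (founders independent,
#' children = midparent + Mendelian-segregation deviation), a shared family
#' environmental effect, and individual noise, with population variance
#' fractions as configured. Raw phenotypes are `loadings x factors` plus
#' covariate effects plus measurement noise scaled so each phenotype has unit
#' variance before covariates. Pre- and post-treatment phenotype pairs are
#' generated with `post = pre + response`, so residualizing post on pre
#' isolates the response factors (and with them the QTL).
#'
#' @param cfg a [sim_config()].
#' @param stratum one element of `gene_drop(cfg)$strata`.
#' @return list with `phenotypes` (data frame: ids, covariates `age`, `sex`,
#'   `bmi`, `smoking`, `vwf`, then `pre_ph*` and `post_ph*` columns) and
#'   `truth_factors` (matrices `pre` and `response` of true factor values,
#'   rows keyed family:individual).
#' @export
simulate_phenotypes <- function(cfg, stratum) {
  ped <- stratum$ped
  ind <- ped$individuals
  n <- nrow(ind)
  keys <- key_of(ind$family_id, ind$individual_id)
  n_fac <- ncol(cfg$factor_loadings)
  qtl <- stratum$truth$qtl
  h2q <- if (is.null(qtl)) 0 else qtl$h2
  h2p <- cfg$polygenic_h2; c2 <- cfg$family_env

  std_dos <- rep(0, n)
  if (h2q > 0 && !is.null(stratum$truth$qtl_dosage)) {
    p <- qtl$maf
    std_dos <- (stratum$truth$qtl_dosage[keys] - 2 * p) / sqrt(2 * p * (1 - p))
    std_dos[is.na(std_dos)] <- 0
  }
  fk_all <- ifelse(ind$father_id == MISSING_CODE, NA,
                   key_of(ind$family_id, ind$father_id))
  mk_all <- ifelse(ind$mother_id == MISSING_CODE, NA,
                   key_of(ind$family_id, ind$mother_id))
  polygenic <- function() {
    # founders N(0,1); children = midparent + Mendelian deviation, resolved
    # generation by generation (vectorized within each sweep)
    g <- stats::setNames(rep(NA_real_, n), keys)
    g[ind$is_founder] <- stats::rnorm(sum(ind$is_founder))
    while (anyNA(g)) {
      ready <- which(is.na(g) & !is.na(g[fk_all]) & !is.na(g[mk_all]))
      if (length(ready) == 0L) stop("unresolvable pedigree in polygenic drop")
      g[ready] <- 0.5 * (g[fk_all[ready]] + g[mk_all[ready]]) +
        stats::rnorm(length(ready), sd = sqrt(0.5))
    }
    g
  }
  one_factor_set <- function(with_qtl) {
    fac <- matrix(0, n, n_fac)
    fam_eff <- stats::rnorm(length(unique(ind$family_id)))
    names(fam_eff) <- unique(ind$family_id)
    for (j in seq_len(n_fac)) {
      qshare <- if (with_qtl && !is.null(qtl) && j == qtl$factor) h2q else 0
      resid <- 1 - qshare - h2p - c2
      fac[, j] <- sqrt(qshare) * std_dos +
        sqrt(h2p) * polygenic() +
        sqrt(c2) * stats::rnorm(length(fam_eff))[match(ind$family_id,
                                                       unique(ind$family_id))] +
        sqrt(resid) * stats::rnorm(n)
    }
    rownames(fac) <- keys
    fac
  }
  fac_pre <- one_factor_set(with_qtl = FALSE)
  fac_resp <- one_factor_set(with_qtl = TRUE)

  covars <- data.frame(
    age = round(stats::rnorm(n, 45, 12)),
    sex = ind$sex,
    bmi = round(stats::rnorm(n, 28, 5), 1),
    smoking = stats::rbinom(n, 1L, 0.2),
    vwf = round(stats::rnorm(n, 100, 25), 1))
  covars$age[covars$age < 21] <- 21

  lam <- cfg$factor_loadings
  uniq <- sqrt(pmax(0, 1 - rowSums(lam^2)))
  ce <- cfg$covariate_effects
  cov_shift <- ce$age * (covars$age - 45) + ce$sex * (covars$sex - 1.5) +
    ce$bmi * (covars$bmi - 28) + ce$smoking * (covars$smoking - 0.2)
  raw_names <- sprintf("ph%02d", seq_len(cfg$n_raw_phenotypes))
  make_raw <- function(fac) {
    raw <- fac %*% t(lam) +
      matrix(stats::rnorm(n * cfg$n_raw_phenotypes), n) %*% diag(uniq)
    raw <- raw + cov_shift
    raw[, cfg$vwf_phenos] <- raw[, cfg$vwf_phenos] +
      (if (is.null(ce$vwf)) 0 else ce$vwf) * (covars$vwf - 100)
    colnames(raw) <- raw_names
    raw
  }
  pre <- make_raw(fac_pre)
  post <- pre + (fac_resp %*% t(lam) +
                   matrix(stats::rnorm(n * cfg$n_raw_phenotypes), n) %*%
                   diag(uniq))
  colnames(pre) <- paste0("pre_", raw_names)
  colnames(post) <- paste0("post_", raw_names)
  phen <- cbind(data.frame(family_id = ind$family_id,
                           individual_id = ind$individual_id,
                           stringsAsFactors = FALSE),
                covars, as.data.frame(pre), as.data.frame(post))
  rownames(phen) <- NULL
  list(phenotypes = phen,
       truth_factors = list(pre = fac_pre, response = fac_resp))
}

#' Simulate a complete study: genotypes, truth and phenotypes per stratum
#'
#' @param cfg a [sim_config()].
#' @return a `gene_drop` object whose strata additionally carry `phenotypes`
#'   and `truth$factors`.
#' @export
sim_study <- function(cfg) {
  gd <- gene_drop(cfg)
  for (s in seq_along(gd$strata)) {
    ph <- simulate_phenotypes(cfg, gd$strata[[s]])
    gd$strata[[s]]$phenotypes <- ph$phenotypes
    gd$strata[[s]]$truth$factors <- ph$truth_factors
  }
  gd
}
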