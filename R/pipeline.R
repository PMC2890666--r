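#' @title End-to-end orchestration
#' @description Sequences the full analysis — pedigree QC, factor phenotypes,
#'   multipoint IBD, Haseman-Elston linkage scan, family-clustered
#'   association for factors with linkage evidence, and linkage-weighted
#'   prioritization — per population stratum, writing every stage's table and
#'   a machine-readable run manifest.
#' @name pipeline
NULL

#' Run configuration with the analysis' standard thresholds
#'
#' All threshold defaults are the analysis constants used throughout:
#' suggestive/significant/highly significant linkage at one-sided p 7.4e-4 /
#' 2e-5 / 3e-7, strict genome-wide Bonferroni 1e-8, FDR level 0.05, region
#' half-width 5 Mb, loading cutoff 0.4, MAF screen 0.02, HWE screen 1e-6.
#'
#' @param sim a [sim_config()] (simulated input), or `NULL` when reading
#'   files.
#' @param ped_path,map_path,pheno_path input files (used when `sim` is NULL).
#' @param group phenotype group analyzed.
#' @param covariates covariate column names for adjustment.
#' @param grid_step IBD/linkage evaluation grid (cM).
#' @param suggestive,significant,highly_significant,bonferroni,fdr_alpha,
#'   region_half_mb,loading_cutoff,maf_min,hwe_min analysis thresholds.
#' @param seed integer seed governing all randomness of the run.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, ped_path = NULL, map_path = NULL,
                       pheno_path = NULL,
                       group = c("post_adjusted_for_pre", "pre", "post"),
                       covariates = c("age", "sex", "bmi", "smoking"),
                       grid_step = 1,
                       suggestive = 7.4e-4, significant = 2e-5,
                       highly_significant = 3e-7, bonferroni = 1e-8,
                       fdr_alpha = 0.05, region_half_mb = 5,
                       loading_cutoff = 0.4, maf_min = 0.02, hwe_min = 1e-6,
                       seed = 1L, out_dir = NULL) {
  group <- match.arg(group)
  thr <- c(suggestive, significant, highly_significant, bonferroni,
           fdr_alpha, region_half_mb, loading_cutoff, maf_min, hwe_min)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (is.null(sim) && (is.null(ped_path) || is.null(map_path) ||
                       is.null(pheno_path))) {
    stop("provide either a sim_config or ped/map/pheno paths")
  }
  structure(list(sim = sim, ped_path = ped_path, map_path = map_path,
                 pheno_path = pheno_path, group = group,
                 covariates = covariates, grid_step = grid_step,
                 suggestive = suggestive, significant = significant,
                 highly_significant = highly_significant,
                 bonferroni = bonferroni, fdr_alpha = fdr_alpha,
                 region_half_mb = region_half_mb,
                 loading_cutoff = loading_cutoff, maf_min = maf_min,
                 hwe_min = hwe_min, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# deterministic polynomial hash of the serialized configuration
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the full combined linkage + association analysis
#'
#' Stages per stratum: pedigree QC (Mendelian check, founder-weighted allele
#' frequencies, marker flags) -> covariate-adjusted Z-scored varimax factors
#' -> multipoint sib-pair IBD on the STR panel -> Haseman-Elston scan ->
#' family-clustered association for every factor with at least one position
#' below the suggestive threshold -> linkage-weighted FDR prioritization.
#' Strata never share data. All randomness derives from `cfg$seed`, so a
#' rerun with the same configuration reproduces every output byte for byte.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list of per-stratum results (`qc`, `factors`, `ibd`,
#'   `scan`, `assoc`, `prioritized`) plus the run `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   group = cfg$group, stages = list())
  note <- function(stage, stratum, rows, info = NULL) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, stratum = stratum, rows = rows, info = info)
  }
  emit <- function(tab, name, stratum) {
    if (!is.null(out_dir)) {
      utils::write.csv(tab, file.path(out_dir,
                                      sprintf("%s_%s.csv", stratum, name)),
                       row.names = FALSE)
    }
  }

  run_stage <- function(stage, stratum, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed for %s: %s", stage, stratum,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(cfg$sim)) {
    study <- run_stage("simulate", "all", sim_study(cfg$sim))
    strata <- study$strata
    note("simulate", "all", sum(vapply(strata, function(s)
      nrow(s$ped$individuals), 0L)))
  } else {
    inp <- run_stage("read", "all",
                     read_pedigree(cfg$ped_path, cfg$map_path))
    phen <- utils::read.csv(cfg$pheno_path, stringsAsFactors = FALSE,
                            colClasses = c(family_id = "character",
                                           individual_id = "character"))
    strata <- list(list(ped = inp$ped, map = inp$map, phenotypes = phen))
    names(strata) <- inp$ped$stratum_label
    note("read", "all", nrow(inp$ped$individuals))
  }

  results <- list()
  for (sname in names(strata)) {
    s <- strata[[sname]]
    # --- QC ---------------------------------------------------------------
    mc <- run_stage("qc", sname, mendelian_check(s$ped))
    ped <- mc$ped
    qc <- run_stage("qc", sname,
                    marker_qc_flags(ped, s$map, cfg$maf_min, cfg$hwe_min))
    emit(qc, "marker_qc", sname)
    note("qc", sname, nrow(qc),
         info = sprintf("%d Mendelian inconsistencies", nrow(mc$inconsistencies)))
    # --- factors ----------------------------------------------------------
    fm <- run_stage("factors", sname, {
      adj <- adjust_covariates(s$phenotypes, covariates = cfg$covariates,
                               group = cfg$group)
      pca_varimax(zscore(adj), group = cfg$group,
                  loading_cutoff = cfg$loading_cutoff)
    })
    emit(cbind(phenotype = rownames(fm$loadings),
               as.data.frame(fm$loadings)), "loadings", sname)
    emit(data.frame(key = rownames(fm$scores), fm$scores), "scores", sname)
    note("factors", sname, fm$retained)
    # --- IBD --------------------------------------------------------------
    traces <- run_stage("ibd", sname,
                        sib_ibd_traces(ped, s$map, grid_step = cfg$grid_step))
    emit(traces$traces, "ibd_traces", sname)
    note("ibd", sname, nrow(traces$traces))
    # --- linkage ----------------------------------------------------------
    scan <- run_stage("linkage", sname,
                      genome_scan(fm$scores, traces, cfg$suggestive,
                                  cfg$significant, cfg$highly_significant))
    emit(scan, "linkage_scan", sname)
    note("linkage", sname, nrow(scan))
    linked <- unique(scan$factor[scan$p < cfg$suggestive])
    # --- association + prioritization, gated on linkage evidence ----------
    assoc_res <- list(); prio_res <- list()
    if (length(linked) == 0L ||
        !any(s$map$class == "SNP")) {
      why <- if (length(linked) == 0L)
        "no factor reached suggestive linkage" else "no SNP panel"
      note("assoc", sname, 0L, info = paste("skipped:", why))
      note("prioritize", sname, 0L, info = paste("skipped:", why))
    } else {
      cmap <- build_combined_map(s$map[s$map$class == "STR", , drop = FALSE],
                                 s$map[s$map$class == "SNP", , drop = FALSE])
      for (fac in linked) {
        at <- run_stage("assoc", sname,
                        genome_assoc(fm$scores[, fac], ped, s$map, qc = qc))
        assoc_res[[fac]] <- at
        emit(at, paste0("assoc_", fac), sname)
        pr <- run_stage("prioritize", sname,
                        prioritize(at, scan, cmap, factor = fac,
                                   alpha = cfg$fdr_alpha,
                                   bonferroni = cfg$bonferroni,
                                   linked_p = cfg$suggestive,
                                   half_width_mb = cfg$region_half_mb))
        prio_res[[fac]] <- pr
        emit(as.data.frame(pr), paste0("prioritized_", fac), sname)
      }
      note("assoc", sname, sum(vapply(assoc_res, nrow, 0L)),
           info = paste("factors:", paste(linked, collapse = ", ")))
      note("prioritize", sname, sum(vapply(prio_res, nrow, 0L)))
    }
    results[[sname]] <- list(
      qc = qc, mendelian = mc$inconsistencies, factors = fm, ibd = traces,
      scan = scan, linked_factors = linked, assoc = assoc_res,
      prioritized = prio_res)
  }
  results$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}
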