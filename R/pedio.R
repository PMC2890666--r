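#' @title Pedigree, map and genotype input/output and marker QC
#' @description Readers and writers for classic linkage-format pedigree files,
#'   pedigree integrity checks, founder-weighted allele frequencies and
#'   SNP-level quality-control flags.
#' @name pedio
NULL

MISSING_CODE <- "0"

key_of <- function(family_id, individual_id) paste(family_id, individual_id, sep = ":")

#' Read a linkage-format pedigree and its marker map
#'
#' The pedigree file is whitespace-delimited with columns
#' `family individual father mother sex` followed by two allele columns per
#' marker (allele code `0` = missing, sex `1` = male, `2` = female,
#' `0` = unknown). The map file is whitespace-delimited with a header and
#' columns `name chrom cm bp` plus an optional fifth column `class`
#' (`STR`/`SNP`; markers with more than two observed alleles default to `STR`,
#' others to `SNP`).
#'
#' @param ped_path path to the pedigree/genotype file.
#' @param map_path path to the marker map file.
#' @param stratum_label label for the population stratum these families belong
#'   to; strata are always analyzed separately.
#' @return a list with components `ped` (a `pedigree_set`) and `map`
#'   (a `genetic_map` data frame with a list column `alleles`).
#' @export
read_pedigree <- function(ped_path, map_path, stratum_label = "stratum1") {
  map <- read_genetic_map(map_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in pedigree file '", ped_path, "'")
  fields <- strsplit(trimws(lines), "\\s+")
  expected <- 5L + 2L * nrow(map)
  nf <- lengths(fields)
  bad <- which(nf != expected)
  if (length(bad) > 0L) {
    stop(sprintf("pedigree line %d has %d fields, expected %d (5 + 2 x %d markers)",
                 bad[1L], nf[bad[1L]], expected, nrow(map)))
  }
  rec <- do.call(rbind, fields)
  individuals <- data.frame(
    family_id = rec[, 1L], individual_id = rec[, 2L],
    father_id = rec[, 3L], mother_id = rec[, 4L],
    sex = as.integer(rec[, 5L]),
    stringsAsFactors = FALSE
  )
  if (!all(individuals$sex %in% c(0L, 1L, 2L))) {
    stop("sex must be coded 1 (male), 2 (female) or 0 (unknown)")
  }
  geno <- rec[, -(1:5), drop = FALSE]
  geno[geno == MISSING_CODE] <- NA_character_
  g1 <- geno[, seq(1L, ncol(geno), by = 2L), drop = FALSE]
  g2 <- geno[, seq(2L, ncol(geno), by = 2L), drop = FALSE]
  colnames(g1) <- colnames(g2) <- map$name
  rownames(g1) <- rownames(g2) <- key_of(individuals$family_id, individuals$individual_id)
  # one missing allele implies the whole genotype is treated as missing
  half <- xor(is.na(g1), is.na(g2))
  g1[half] <- NA_character_
  g2[half] <- NA_character_
  # fill map allele sets from observed data where absent
  map$alleles <- lapply(seq_len(nrow(map)), function(j) {
    obs <- sort(unique(stats::na.omit(c(g1[, j], g2[, j]))))
    known <- map$alleles[[j]]
    if (length(known) == 0L) obs else {
      extra <- setdiff(obs, known)
      if (length(extra) > 0L) {
        stop(sprintf("marker '%s': allele(s) %s not in map allele set",
                     map$name[j], paste(extra, collapse = ", ")))
      }
      known
    }
  })
  if (any(is.na(map$class))) {
    nall <- lengths(map$alleles)
    map$class[is.na(map$class)] <- ifelse(nall > 2L, "STR", "SNP")
  }
  ped <- new_pedigree_set(individuals, g1, g2, stratum_label)
  list(ped = ped, map = map)
}

read_genetic_map <- function(map_path) {
  map <- utils::read.table(map_path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(map) == 0L) stop("no records in map file '", map_path, "'")
  need <- c("name", "chrom", "cm", "bp")
  if (!all(need %in% names(map))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  map$chrom <- as.integer(map$chrom)
  if (!"class" %in% names(map)) map$class <- NA_character_
  map <- map[, c("name", "chrom", "cm", "bp", "class")]
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    if (is.unsorted(map$cm[sel]) || is.unsorted(map$bp[sel])) {
      stop("map positions must be non-decreasing within chromosome ", ch)
    }
  }
  map$alleles <- replicate(nrow(map), character(0), simplify = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  map
}

new_pedigree_set <- function(individuals, g1, g2, stratum_label) {
  individuals$is_founder <- individuals$father_id == MISSING_CODE &
    individuals$mother_id == MISSING_CODE
  one_parent <- xor(individuals$father_id == MISSING_CODE,
                    individuals$mother_id == MISSING_CODE)
  if (any(one_parent)) {
    stop("individuals must have both parents present or both missing: ",
         paste(individuals$individual_id[one_parent], collapse = ", "))
  }
  validate_parents(individuals)
  ped <- structure(
    list(individuals = individuals, g1 = g1, g2 = g2,
         stratum_label = stratum_label),
    class = "pedigree_set"
  )
  ped
}

validate_parents <- function(ind) {
  keys <- key_of(ind$family_id, ind$individual_id)
  for (i in seq_len(nrow(ind))) {
    for (p in c(ind$father_id[i], ind$mother_id[i])) {
      if (p != MISSING_CODE && !(key_of(ind$family_id[i], p) %in% keys)) {
        stop(sprintf("individual %s in family %s: parent %s not in the family",
                     ind$individual_id[i], ind$family_id[i], p))
      }
    }
  }
  # cycle check: no individual may be its own ancestor
  idx <- stats::setNames(seq_len(nrow(ind)), keys)
  for (i in seq_len(nrow(ind))) {
    frontier <- i
    seen <- integer(0)
    while (length(frontier) > 0L) {
      j <- frontier[1L]; frontier <- frontier[-1L]
      parents <- c(ind$father_id[j], ind$mother_id[j])
      parents <- parents[parents != MISSING_CODE]
      pj <- idx[key_of(ind$family_id[j], parents)]
      if (i %in% pj) {
        stop(sprintf("pedigree cycle: individual %s in family %s is its own ancestor",
                     ind$individual_id[i], ind$family_id[i]))
      }
      pj <- setdiff(pj, seen)
      seen <- c(seen, pj)
      frontier <- c(frontier, pj)
    }
  }
  invisible(TRUE)
}

#' @export
print.pedigree_set <- function(x, ...) {
  cat(sprintf("<pedigree_set '%s': %d individuals, %d families, %d founders, %d markers>\n",
              x$stratum_label, nrow(x$individuals),
              length(unique(x$individuals$family_id)),
              sum(x$individuals$is_founder), ncol(x$g1)))
  invisible(x)
}

#' Write a pedigree set and map back to linkage-format files
#'
#' Inverse of [read_pedigree()]; writing then re-reading reproduces the
#' pedigree structure and genotypes exactly. Output uses the C locale decimal
#' point regardless of session locale.
#'
#' @param ped a `pedigree_set`.
#' @param map the matching `genetic_map`.
#' @param ped_path,map_path output paths.
#' @export
write_pedigree <- function(ped, map, ped_path, map_path) {
  g1 <- ped$g1; g2 <- ped$g2
  g1[is.na(g1)] <- MISSING_CODE
  g2[is.na(g2)] <- MISSING_CODE
  geno <- matrix(MISSING_CODE, nrow(g1), 2L * ncol(g1))
  geno[, seq(1L, ncol(geno), by = 2L)] <- g1
  geno[, seq(2L, ncol(geno), by = 2L)] <- g2
  ind <- ped$individuals
  rec <- cbind(ind$family_id, ind$individual_id, ind$father_id, ind$mother_id,
               ind$sex, geno)
  writeLines(apply(rec, 1L, paste, collapse = " "), ped_path)
  mp <- data.frame(name = map$name, chrom = map$chrom,
                   cm = formatC(map$cm, format = "g", digits = 15),
                   bp = format(map$bp, scientific = FALSE, trim = TRUE),
                   class = map$class)
  utils::write.table(mp, map_path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(NULL)
}

#' Mendelian-consistency check
#'
#' Flags every (family, individual, marker) where a child's genotype cannot be
#' formed by one allele from each typed parent. Markers where a parent is
#' untyped are checked against the typed parent only; children with both
#' parents untyped at a marker are unverifiable there and never flagged.
#' Following the source policy of removing all persons with inconsistencies
#' prior to analysis, the returned pedigree drops every flagged individual
#' (children of a removed parent have that parent link set to missing).
#'
#' @param ped a `pedigree_set`.
#' @return list with `inconsistencies` (data frame: family_id, individual_id,
#'   marker) and `ped` (the filtered `pedigree_set`).
#' @export
mendelian_check <- function(ped) {
  ind <- ped$individuals
  keys <- key_of(ind$family_id, ind$individual_id)
  out <- list()
  for (i in seq_len(nrow(ind))) {
    if (ind$is_founder[i]) next
    fk <- key_of(ind$family_id[i], ind$father_id[i])
    mk <- key_of(ind$family_id[i], ind$mother_id[i])
    c1 <- ped$g1[i, ]; c2 <- ped$g2[i, ]
    f1 <- ped$g1[fk, ]; f2 <- ped$g2[fk, ]
    m1 <- ped$g1[mk, ]; m2 <- ped$g2[mk, ]
    typed <- !is.na(c1)
    ok <- rep(TRUE, length(c1))
    bothp <- typed & !is.na(f1) & !is.na(m1)
    ok[bothp] <- ((c1 %in_pair% cbind(f1, f2)) & (c2 %in_pair% cbind(m1, m2)) |
                  (c2 %in_pair% cbind(f1, f2)) & (c1 %in_pair% cbind(m1, m2)))[bothp]
    fonly <- typed & !is.na(f1) & is.na(m1)
    ok[fonly] <- ((c1 %in_pair% cbind(f1, f2)) | (c2 %in_pair% cbind(f1, f2)))[fonly]
    monly <- typed & is.na(f1) & !is.na(m1)
    ok[monly] <- ((c1 %in_pair% cbind(m1, m2)) | (c2 %in_pair% cbind(m1, m2)))[monly]
    bad <- which(!ok)
    if (length(bad) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        family_id = ind$family_id[i], individual_id = ind$individual_id[i],
        marker = colnames(ped$g1)[bad], stringsAsFactors = FALSE)
    }
  }
  inconsistencies <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(family_id = character(0), individual_id = character(0),
               marker = character(0))
  if (nrow(inconsistencies) > 0L) {
    drop_keys <- unique(key_of(inconsistencies$family_id,
                               inconsistencies$individual_id))
    keep <- !(keys %in% drop_keys)
    ind2 <- ind[keep, , drop = FALSE]
    # orphaned parent links become missing; founder status recomputed
    for (j in seq_len(nrow(ind2))) {
      if (ind2$father_id[j] != MISSING_CODE &&
          key_of(ind2$family_id[j], ind2$father_id[j]) %in% drop_keys) {
        ind2$father_id[j] <- MISSING_CODE
        ind2$mother_id[j] <- MISSING_CODE
      } else if (ind2$mother_id[j] != MISSING_CODE &&
                 key_of(ind2$family_id[j], ind2$mother_id[j]) %in% drop_keys) {
        ind2$father_id[j] <- MISSING_CODE
        ind2$mother_id[j] <- MISSING_CODE
      }
    }
    ind2$is_founder <- NULL
    ped2 <- new_pedigree_set(ind2, ped$g1[keep, , drop = FALSE],
                             ped$g2[keep, , drop = FALSE], ped$stratum_label)
  } else {
    ped2 <- ped
  }
  list(inconsistencies = inconsistencies, ped = ped2)
}

# vectorized membership of an allele in a 2-column allele-pair matrix
`%in_pair%` <- function(a, pair) {
  !is.na(a) & (a == pair[, 1L] | a == pair[, 2L])
}

#' Founder-weighted allele frequencies
#'
#' Allele counts among each family's founders are first reduced to per-family
#' allele proportions; families are then combined with weights proportional to
#' the number of founders each contains. Families whose founders are all
#' untyped at the marker contribute nothing (weights renormalized over
#' informative families).
#'
#' @param ped a `pedigree_set`.
#' @param marker marker name.
#' @return named numeric vector of allele frequencies summing to 1.
#' @export
founder_weighted_allele_freq <- function(ped, marker) {
  if (!marker %in% colnames(ped$g1)) stop("unknown marker '", marker, "'")
  ind <- ped$individuals
  fams <- split(seq_len(nrow(ind)), ind$family_id)
  labels <- sort(unique(stats::na.omit(c(ped$g1[, marker], ped$g2[, marker]))))
  if (length(labels) == 0L) stop("no data at marker '", marker, "'")
  props <- list(); wts <- numeric(0)
  for (fam in names(fams)) {
    rows <- fams[[fam]]
    fdr <- rows[ind$is_founder[rows]]
    alle <- c(ped$g1[fdr, marker], ped$g2[fdr, marker])
    alle <- alle[!is.na(alle)]
    if (length(alle) == 0L) next
    tab <- table(factor(alle, levels = labels))
    props[[fam]] <- as.numeric(tab) / length(alle)
    wts <- c(wts, sum(ind$is_founder[rows]))
  }
  if (length(props) == 0L) stop("no data at marker '", marker, "' (no typed founders)")
  w <- wts / sum(wts)
  freq <- colSums(do.call(rbind, props) * w)
  stats::setNames(freq, labels)
}

#' Marker quality-control flags for biallelic SNPs
#'
#' Flags markers with minor allele frequency below `maf_min` and markers with
#' severe Hardy-Weinberg disequilibrium (1-df chi-square goodness of fit,
#' founders only, no continuity correction, p below `hwe_min`). Flags are
#' advisory: flagged markers remain in all analyses. Monomorphic markers get
#' `low_maf = TRUE` and an HWE p of 1 (the test is undefined).
#'
#' @param ped a `pedigree_set`.
#' @param map the matching `genetic_map`; only markers with `class == "SNP"`
#'   are tested.
#' @param maf_min minor-allele-frequency screen (default 0.02).
#' @param hwe_min HWE p-value screen (default 1e-6).
#' @return data frame: marker, maf, hwe_p, low_maf, hwe_fail.
#' @export
marker_qc_flags <- function(ped, map, maf_min = 0.02, hwe_min = 1e-6) {
  snps <- map$name[map$class == "SNP"]
  ind <- ped$individuals
  res <- lapply(snps, function(m) {
    freq <- tryCatch(founder_weighted_allele_freq(ped, m), error = function(e) NULL)
    if (is.null(freq)) {
      return(data.frame(marker = m, maf = NA_real_, hwe_p = NA_real_,
                        low_maf = NA, hwe_fail = NA))
    }
    if (length(freq) > 2L) stop("marker '", m, "' is not biallelic")
    maf <- if (length(freq) == 1L) 0 else min(freq)
    hp <- hwe_chisq_p(ped, m)
    data.frame(marker = m, maf = maf, hwe_p = hp,
               low_maf = maf < maf_min, hwe_fail = hp < hwe_min)
  })
  do.call(rbind, res)
}

# 1-df HWE goodness-of-fit chi-square on founder genotype counts
hwe_chisq_p <- function(ped, marker) {
  ind <- ped$individuals
  fdr <- which(ind$is_founder)
  a1 <- ped$g1[fdr, marker]; a2 <- ped$g2[fdr, marker]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) == 0L) return(NA_real_)
  labels <- sort(unique(c(a1, a2)))
  if (length(labels) < 2L) return(1)
  A <- labels[1L]
  nAA <- sum(a1 == A & a2 == A)
  nBB <- sum(a1 != A & a2 != A)
  nAB <- length(a1) - nAA - nBB
  n <- length(a1)
  p <- (2 * nAA + nAB) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  x2 <- sum((c(nAA, nAB, nBB) - e)^2 / e)
  stats::pchisq(x2, df = 1L, lower.tail = FALSE)
}

#' All full-sib pairs of a pedigree set
#'
#' Full sibs share both (non-missing) parents; every pair within a sibship is
#' emitted, so a sibship of `k` contributes `choose(k, 2)` pairs.
#'
#' @param ped a `pedigree_set`.
#' @return data frame: pair_id, family_id, id1, id2, father_id, mother_id.
#' @export
sib_pairs <- function(ped) {
  ind <- ped$individuals
  nonf <- ind[!ind$is_founder, , drop = FALSE]
  grp <- split(nonf, list(nonf$family_id, nonf$father_id, nonf$mother_id),
               drop = TRUE)
  out <- list()
  for (g in grp) {
    if (nrow(g) < 2L) next
    cmb <- utils::combn(order(g$individual_id), 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      out[[length(out) + 1L]] <- data.frame(
        family_id = g$family_id[i], id1 = g$individual_id[i],
        id2 = g$individual_id[j], father_id = g$father_id[i],
        mother_id = g$mother_id[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pair_id = character(0), family_id = character(0),
                      id1 = character(0), id2 = character(0),
                      father_id = character(0), mother_id = character(0)))
  }
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$family_id, pairs$id1, pairs$id2), , drop = FALSE]
  pairs <- cbind(pair_id = paste(pairs$family_id, pairs$id1, pairs$id2, sep = ":"),
                 pairs)
  rownames(pairs) <- NULL
  pairs
}
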