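#' @title Multipoint IBD estimation for full sib pairs
#' @description Single-point emission likelihoods and a hidden Markov model
#'   over allele sharing identical by descent (IBD). Each parental meiosis
#'   pair defines a two-state sharing chain with flip probability
#'   `psi = 2 theta (1 - theta)`; the implementation runs the exact four-state
#'   product chain of the two parents (states `00, 01, 10, 11` of
#'   maternal/paternal sharing) and collapses posteriors to IBD counts
#'   0/1/2. Sharing the maternal versus the paternal meiosis is
#'   distinguishable when parents are typed, which is why the product chain —
#'   not a symmetric three-state chain — is the exact formulation.
#' @name ibd
NULL

IBD_PRIOR <- c(0.25, 0.5, 0.25)

#' Sib-pair IBD transition matrix
#'
#' Three-state transition matrix of IBD counts over a map interval with
#' recombination fraction `theta`, built from two independent per-parent
#' sharing chains each flipping with probability `psi = 2 theta (1 - theta)`.
#' At `theta = 0` it is the identity; at `theta = 0.5` every row equals the
#' stationary prior (1/4, 1/2, 1/4).
#'
#' @param theta recombination fraction in `[0, 0.5]`.
#' @return 3x3 row-stochastic matrix over IBD counts 0, 1, 2.
#' @export
sib_transition_matrix <- function(theta) {
  if (theta < 0 || theta > 0.5) stop("theta must lie in [0, 0.5]")
  psi <- 2 * theta * (1 - theta)
  s <- 1 - psi
  matrix(c(s^2,       2 * s * psi,    psi^2,
           s * psi,   s^2 + psi^2,    s * psi,
           psi^2,     2 * s * psi,    s^2),
         nrow = 3L, byrow = TRUE,
         dimnames = list(paste0("ibd", 0:2), paste0("ibd", 0:2)))
}

# 2-state per-parent sharing transition and its 4-state product
parent_chain <- function(theta) {
  psi <- 2 * theta * (1 - theta)
  matrix(c(1 - psi, psi, psi, 1 - psi), 2L, 2L, byrow = TRUE)
}

product_transition <- function(theta) {
  P <- parent_chain(theta)
  kronecker(P, P)   # states in order (m,p) = 00, 01, 10, 11
}

hwe_geno_prob <- function(g, freqs) {
  pa <- freqs[g[1L]]; pb <- freqs[g[2L]]
  if (any(is.na(c(pa, pb)))) {
    stop("allele '", paste(g[is.na(c(pa, pb))], collapse = "','"),
         "' absent from frequency vector")
  }
  unname(if (g[1L] == g[2L]) pa^2 else 2 * pa * pb)
}

# P(g1, g2 | IBD = k) with untyped parents, population-frequency formulas
emission_popfreq <- function(g1, g2, freqs) {
  miss1 <- is.null(g1) || any(is.na(g1))
  miss2 <- is.null(g2) || any(is.na(g2))
  if (miss1 && miss2) return(c(1, 1, 1))
  if (miss1) return(rep(hwe_geno_prob(g2, freqs), 3L))
  if (miss2) return(rep(hwe_geno_prob(g1, freqs), 3L))
  e0 <- hwe_geno_prob(g1, freqs) * hwe_geno_prob(g2, freqs)
  e2 <- if (setequal_pair(g1, g2)) hwe_geno_prob(g1, freqs) else 0
  shared <- intersect(unique(g1), unique(g2))
  e1 <- 0
  for (s in shared) {
    o1 <- other_allele(g1, s); o2 <- other_allele(g2, s)
    e1 <- e1 + unname(freqs[s] * freqs[o1] * freqs[o2])
  }
  c(e0, e1, e2)
}

setequal_pair <- function(a, b) {
  (a[1L] == b[1L] && a[2L] == b[2L]) || (a[1L] == b[2L] && a[2L] == b[1L])
}

other_allele <- function(g, s) if (g[1L] == s) g[2L] else g[1L]

# P(g1, g2 | sharing config, parental genotypes) by enumerating transmissions
emission_typed_config <- function(g1, g2, gm, gf, sm, sp) {
  match_g <- function(g, a, b) {
    if (is.null(g) || any(is.na(g))) return(1)
    as.numeric((g[1L] == a && g[2L] == b) || (g[1L] == b && g[2L] == a))
  }
  tot <- 0
  for (i1 in 1:2) for (j1 in 1:2) {
    i2 <- if (sm == 1L) i1 else 3L - i1
    j2 <- if (sp == 1L) j1 else 3L - j1
    tot <- tot + match_g(g1, gm[i1], gf[j1]) * match_g(g2, gm[i2], gf[j2])
  }
  tot / 4
}

all_genotypes <- function(alleles) {
  k <- length(alleles)
  out <- list()
  for (i in seq_len(k)) for (j in i:k) {
    out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  }
  out
}

# emission over the 4 sharing configs (00, 01, 10, 11); parents may each be
# typed, or untyped (then marginalized over Hardy-Weinberg genotypes)
emission_configs <- function(g1, g2, gm, gf, freqs) {
  m_typed <- !(is.null(gm) || any(is.na(gm)))
  f_typed <- !(is.null(gf) || any(is.na(gf)))
  if (!m_typed && !f_typed) {
    e <- emission_popfreq(g1, g2, freqs)
    return(c(e[1L], e[2L], e[2L], e[3L]))
  }
  genos <- all_genotypes(names(freqs))
  probs <- vapply(genos, hwe_geno_prob, 0, freqs = freqs)
  gm_list <- if (m_typed) list(list(g = gm, p = 1)) else
    Map(function(g, p) list(g = g, p = p), genos, probs)
  gf_list <- if (f_typed) list(list(g = gf, p = 1)) else
    Map(function(g, p) list(g = g, p = p), genos, probs)
  e <- c(0, 0, 0, 0)
  configs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (gm_i in gm_list) for (gf_i in gf_list) {
    w <- gm_i$p * gf_i$p
    for (ci in 1:4) {
      e[ci] <- e[ci] + w * emission_typed_config(
        g1, g2, gm_i$g, gf_i$g, configs[[ci]][1L], configs[[ci]][2L])
    }
  }
  e
}

#' Single-point sib-pair emission likelihoods
#'
#' `P(genotype data | IBD = k)` for `k = 0, 1, 2` at one marker. With untyped
#' parents the population-frequency formulas for sib-pair genotype
#' probabilities conditional on IBD are used; with one or both parents typed,
#' parental transmissions consistent with each sharing configuration are
#' enumerated (untyped parents marginalized over Hardy-Weinberg genotype
#' probabilities). Missing sib genotypes are marginalized, so a pair with
#' both sibs untyped returns `(1, 1, 1)`. For IBD 1 the value is the average
#' over the two single-parent sharing configurations.
#'
#' @param g1,g2 length-2 character vectors of alleles (or `NA`/`NULL` when
#'   missing).
#' @param gm,gf optional maternal/paternal genotypes.
#' @param freqs named allele frequency vector (from
#'   [founder_weighted_allele_freq()]).
#' @return numeric `(e0, e1, e2)`.
#' @export
singlepoint_emission <- function(g1, g2, gm = NULL, gf = NULL, freqs) {
  for (g in list(g1, g2, gm, gf)) {
    if (!is.null(g) && !any(is.na(g)) && !all(g %in% names(freqs))) {
      stop("allele '", paste(setdiff(g, names(freqs)), collapse = "','"),
           "' absent from frequency vector")
    }
  }
  e4 <- emission_configs(g1, g2, gm, gf, freqs)
  c(e0 = e4[1L], e1 = (e4[2L] + e4[3L]) / 2, e2 = e4[4L])
}

#' Multipoint IBD posteriors along one chromosome
#'
#' Forward-backward over the four-state per-parent sharing chain, given
#' per-marker emission likelihoods and marker positions in cM (Haldane map).
#' Posteriors are also evaluated at off-marker grid positions (uninformative
#' emissions there). Returns proper posterior distributions over IBD counts
#' and the mean sharing trace `pihat = p1/2 + p2`.
#'
#' @param emissions numeric matrix, markers x 3 (`e0,e1,e2`; the two
#'   single-parent configurations assumed exchangeable) or markers x 4
#'   (`e00,e01,e10,e11`, exact with typed parents).
#' @param marker_cm marker positions (cM), non-decreasing.
#' @param grid_cm optional extra evaluation positions (cM).
#' @return data frame: pos_cm, at_marker, p0, p1, p2, pihat.
#' @export
multipoint_pihat <- function(emissions, marker_cm, grid_cm = NULL) {
  emissions <- as.matrix(emissions)
  if (length(marker_cm) != nrow(emissions)) {
    stop("emissions rows must match marker positions")
  }
  if (is.unsorted(marker_cm)) stop("marker positions must be non-decreasing")
  if (ncol(emissions) == 3L) {
    emissions <- cbind(emissions[, 1L], emissions[, 2L],
                       emissions[, 2L], emissions[, 3L])
  } else if (ncol(emissions) != 4L) {
    stop("emissions must have 3 or 4 columns")
  }
  pos <- sort(unique(c(marker_cm, grid_cm)))
  E <- matrix(1, length(pos), 4L)
  mi <- match(round(marker_cm, 9L), round(pos, 9L))
  # multiple markers can share a position; multiply their emissions
  for (r in seq_along(mi)) E[mi[r], ] <- E[mi[r], ] * emissions[r, ]
  trans <- lapply(haldane_theta(diff(pos)), product_transition)
  post <- product_forward_backward(E, trans)
  p0 <- post[, 1L]; p1 <- post[, 2L] + post[, 3L]; p2 <- post[, 4L]
  data.frame(pos_cm = pos, at_marker = pos %in% marker_cm,
             p0 = p0, p1 = p1, p2 = p2, pihat = p1 / 2 + p2)
}

# scaled forward-backward on the 4-state sharing chain
product_forward_backward <- function(E, trans) {
  P <- nrow(E)
  prior <- rep(0.25, 4L)
  fwd <- matrix(0, P, 4L); bwd <- matrix(0, P, 4L)
  f <- prior * E[1L, ]; fwd[1L, ] <- f / sum(f)
  if (P > 1L) for (t in 2:P) {
    f <- as.vector(crossprod(trans[[t - 1L]], fwd[t - 1L, ])) * E[t, ]
    fwd[t, ] <- f / sum(f)
  }
  bwd[P, ] <- 1
  if (P > 1L) for (t in (P - 1L):1L) {
    b <- as.vector(trans[[t]] %*% (E[t + 1L, ] * bwd[t + 1L, ]))
    bwd[t, ] <- b / sum(b)
  }
  post <- fwd * bwd
  post / rowSums(post)
}

#' Multipoint IBD traces for every full sib pair of a pedigree set
#'
#' Runs [multipoint_pihat()] for all full-sib pairs over the markers of the
#' requested class (the sparse STR linkage panel by default), using parental
#' genotypes when typed and founder-weighted allele frequencies for the
#' emission model. The evaluation grid is every `grid_step` cM plus all
#' marker positions.
#'
#' @param ped a `pedigree_set`.
#' @param map the matching `genetic_map`.
#' @param grid_step off-marker grid spacing in cM (default 1).
#' @param marker_class marker class used for IBD estimation (default "STR").
#' @param freqs optional named list of allele-frequency vectors per marker;
#'   computed by [founder_weighted_allele_freq()] when absent.
#' @return an `ibd_traces` object: list with `pairs` (see [sib_pairs()]) and
#'   `traces`, a long data frame (pair_id, chrom, pos_cm, at_marker,
#'   p0, p1, p2, pihat).
#' @export
sib_ibd_traces <- function(ped, map, grid_step = 1, marker_class = "STR",
                           freqs = NULL) {
  use <- map[map$class %in% marker_class, , drop = FALSE]
  if (nrow(use) == 0L) stop("no markers of class ", paste(marker_class, collapse = "/"))
  pairs <- sib_pairs(ped)
  if (nrow(pairs) == 0L) stop("no full sib pairs in pedigree set")
  if (is.null(freqs)) {
    freqs <- lapply(use$name, function(m) founder_weighted_allele_freq(ped, m))
    names(freqs) <- use$name
  }
  out <- vector("list", 0L)
  for (ch in unique(use$chrom)) {
    sub <- use[use$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$cm), , drop = FALSE]
    grid <- seq(0, max(sub$cm) + grid_step, by = grid_step)
    pos <- sort(unique(c(sub$cm, grid)))
    mi <- match(round(sub$cm, 9L), round(pos, 9L))
    trans <- lapply(haldane_theta(diff(pos)), product_transition)
    at_marker <- pos %in% sub$cm
    for (r in seq_len(nrow(pairs))) {
      fam <- pairs$family_id[r]
      k1 <- key_of(fam, pairs$id1[r]); k2 <- key_of(fam, pairs$id2[r])
      km <- key_of(fam, pairs$mother_id[r]); kf <- key_of(fam, pairs$father_id[r])
      E <- matrix(1, length(pos), 4L)
      for (j in seq_len(nrow(sub))) {
        mk <- sub$name[j]
        E[mi[j], ] <- E[mi[j], ] * emission_configs(
          g1 = c(ped$g1[k1, mk], ped$g2[k1, mk]),
          g2 = c(ped$g1[k2, mk], ped$g2[k2, mk]),
          gm = c(ped$g1[km, mk], ped$g2[km, mk]),
          gf = c(ped$g1[kf, mk], ped$g2[kf, mk]),
          freqs = freqs[[mk]])
      }
      post <- product_forward_backward(E, trans)
      p1 <- post[, 2L] + post[, 3L]
      tr <- data.frame(pair_id = pairs$pair_id[r], chrom = ch, pos_cm = pos,
                       at_marker = at_marker, p0 = post[, 1L], p1 = p1,
                       p2 = post[, 4L], pihat = p1 / 2 + post[, 4L],
                       stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- tr
    }
  }
  traces <- do.call(rbind, out)
  rownames(traces) <- NULL
  structure(list(pairs = pairs, traces = traces), class = "ibd_traces")
}

#' @export
print.ibd_traces <- function(x, ...) {
  cat(sprintf("<ibd_traces: %d pairs, %d chromosome(s), %d positions/pair>\n",
              nrow(x$pairs), length(unique(x$traces$chrom)),
              nrow(x$traces) / nrow(x$pairs)))
  invisible(x)
}
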