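# Independent oracles used across the suite. These deliberately share no code
# with the package: brute-force enumeration and closed-form arithmetic only.

# --- exhaustive sib-pair emission oracle ------------------------------------
# P(g1, g2 | sharing config (sm, sp)) by enumerating parental genotypes
# (Hardy-Weinberg weighted when untyped) and all 4 transmission choices.
oracle_emission_configs <- function(g1, g2, gm, gf, freqs) {
  alleles <- names(freqs)
  genos <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles)) {
    genos[[length(genos) + 1L]] <- c(alleles[i], alleles[j])
  }
  hwe <- function(g) {
    if (g[1] == g[2]) freqs[[g[1]]]^2 else 2 * freqs[[g[1]]] * freqs[[g[2]]]
  }
  matches <- function(g, a, b) {
    if (is.null(g) || any(is.na(g))) return(1)
    as.numeric((g[1] == a && g[2] == b) || (g[1] == b && g[2] == a))
  }
  gm_set <- if (is.null(gm) || any(is.na(gm))) genos else list(gm)
  gf_set <- if (is.null(gf) || any(is.na(gf))) genos else list(gf)
  gm_w <- if (length(gm_set) > 1L) vapply(gm_set, hwe, 0) else 1
  gf_w <- if (length(gf_set) > 1L) vapply(gf_set, hwe, 0) else 1
  out <- c(0, 0, 0, 0)
  cfgs <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (a in seq_along(gm_set)) for (b in seq_along(gf_set)) {
    M <- gm_set[[a]]; F <- gf_set[[b]]
    for (ci in 1:4) {
      sm <- cfgs[[ci]][1]; sp <- cfgs[[ci]][2]
      tot <- 0
      for (i1 in 1:2) for (j1 in 1:2) {
        i2 <- if (sm == 1) i1 else 3 - i1
        j2 <- if (sp == 1) j1 else 3 - j1
        tot <- tot + matches(g1, M[i1], F[j1]) * matches(g2, M[i2], F[j2])
      }
      out[ci] <- out[ci] + gm_w[a] * gf_w[b] * tot / 4
    }
  }
  out
}

# --- brute-force multipoint posterior ---------------------------------------
# Sums over all per-parent sharing paths (2^m per parent). e4 is m x 4 with
# config order (00, 01, 10, 11); thetas are the m-1 inter-marker fractions.
oracle_multipoint_posterior <- function(e4, thetas) {
  m <- nrow(e4)
  psi <- 2 * thetas * (1 - thetas)
  paths <- as.matrix(expand.grid(rep(list(0:1), m)))
  path_prob <- function(s) {
    pr <- 0.5
    if (m > 1) for (t in 2:m) {
      pr <- pr * if (s[t] == s[t - 1]) 1 - psi[t - 1] else psi[t - 1]
    }
    pr
  }
  post <- matrix(0, m, 4)
  total <- 0
  for (a in seq_len(nrow(paths))) for (b in seq_len(nrow(paths))) {
    sm <- paths[a, ]; sp <- paths[b, ]
    w <- path_prob(sm) * path_prob(sp)
    for (t in 1:m) w <- w * e4[t, 1 + sm[t] * 2 + sp[t]]
    if (w == 0) next
    total <- total + w
    for (t in 1:m) post[t, 1 + sm[t] * 2 + sp[t]] <-
        post[t, 1 + sm[t] * 2 + sp[t]] + w
  }
  post / total
}

# collapse a 4-config posterior matrix to IBD counts (p0, p1, p2)
collapse_ibd <- function(post4) {
  cbind(p0 = post4[, 1], p1 = post4[, 2] + post4[, 3], p2 = post4[, 4])
}

# --- hand Benjamini-Hochberg ------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- brute-force varimax over a planar rotation -----------------------------
oracle_varimax_2f <- function(L, step = 1e-4) {
  crit <- function(M) {
    sum(apply(M^2, 2, function(col) mean((col - mean(col))^2)))
  }
  best <- -Inf
  for (a in seq(0, pi / 2, by = step)) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    best <- max(best, crit(L %*% R))
  }
  best
}

# --- closed-form simple regression ------------------------------------------
oracle_ols <- function(y, x) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  s2 <- sum(r^2) / (length(y) - 2)
  se <- sqrt(s2 * diag(solve(t(X) %*% X)))
  list(alpha = unname(b[1]), beta = unname(b[2]), se_beta = unname(se[2]),
       t = unname(b[2] / se[2]), resid = as.vector(r))
}
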