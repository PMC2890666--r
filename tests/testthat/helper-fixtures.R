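# Small programmatic fixtures.

# write PED/MAP text to temp files and read them back through the package
ped_from_text <- function(ped_lines, map_lines, stratum = "toy") {
  pf <- tempfile(fileext = ".ped"); mf <- tempfile(fileext = ".map")
  writeLines(ped_lines, pf)
  writeLines(map_lines, mf)
  read_pedigree(pf, mf, stratum_label = stratum)
}

toy_map2 <- c("name chrom cm bp class",
              "M1 1 10 1000000 STR",
              "M2 1 20 2000000 STR")

# one nuclear family: parents 1/2, sibs 3/4; genotypes per marker as strings
toy_family_lines <- function(g = c("A A", "A B", "A A", "A B"),
                             g2 = c("C C", "C D", "C C", "C D")) {
  c(paste("1 1 0 0 1", g[1], g2[1]),
    paste("1 2 0 0 2", g[2], g2[2]),
    paste("1 3 1 2 1", g[3], g2[3]),
    paste("1 4 1 2 2", g[4], g2[4]))
}

# pedigree of independent founder "families" with prescribed SNP genotype
# counts (for allele-frequency / HWE fixtures); one biallelic marker "S"
founders_with_counts <- function(n_aa, n_ab, n_bb) {
  g <- c(rep("A A", n_aa), rep("A B", n_ab), rep("B B", n_bb))
  lines <- sprintf("%d 1 0 0 1 %s", seq_along(g), g)
  ped_from_text(lines, c("name chrom cm bp class", "S 1 0 100 SNP"))
}

# small single-stratum simulation used by several suites
small_sim <- function(n_families = 60, seed = 42, qtl = NULL,
                      snp_spacing_kb = 0, len = 100, sibs = 2) {
  cfg <- sim_config(n_families = n_families, sibs_per_family = sibs,
                    n_strata = 1, snp_spacing_kb = snp_spacing_kb,
                    chromosomes = data.frame(length_cm = len, length_mb = len),
                    qtl = qtl, seed = seed)
  sim_study(cfg)$strata[[1]]
}
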