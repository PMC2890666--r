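Package: sibscan
Title: Combined Sib-Pair Linkage and Family-Based Association Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based gene mapping for correlated quantitative phenotypes,
    combining classical sib-pair linkage with dense-panel association and a
    linkage-weighted false discovery rate. Provides linkage-format pedigree
    input/output with Mendelian-consistency checks and founder-weighted allele
    frequencies; covariate adjustment, Z-scoring and varimax-rotated principal
    component phenotypes; multipoint identity-by-descent estimation for full
    sib pairs by a hidden Markov model on the Haldane map; Haseman-Elston
    regression genome scans with Lander-Kruglyak significance classes;
    per-SNP association under a family random-intercept model with
    cluster-robust (sandwich) variance; prioritization of association signals
    by weights derived from interpolated linkage traces with Storey q-values
    and region-specific Bonferroni screens; and a gene-drop simulator of
    nuclear-family marker and phenotype data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
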