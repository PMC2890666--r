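---
title: "Combined sib-pair linkage and family-based association with linkage-weighted FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined sib-pair linkage and family-based association with linkage-weighted FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`sibscan` maps quantitative trait loci for batteries of correlated phenotypes
measured in nuclear families — the motivating application is platelet-function
panels measured before and after an aspirin trial in siblings ascertained
through a proband. Because dozens of raw phenotypes cluster by biological
pathway, the unit of analysis is not a raw phenotype but a **varimax-rotated
principal component factor** of covariate-adjusted, Z-scored phenotypes.
Each factor is scanned for linkage with **Haseman–Elston sib-pair regression**
on multipoint IBD sharing estimated from a sparse multiallelic marker panel;
factors with linkage evidence are then tested SNP by SNP under a **family
random-intercept linear model** with a cluster-robust (sandwich) variance;
finally the genome-wide association p-values are **re-weighted by the linkage
trace** (through the standard normal CDF, normalized to mean one) and
converted to **Storey q-values**, so that regions with independent linkage
evidence need less association evidence to be prioritized. Every stage is
validated against a built-in gene-drop simulator that generates families,
marker panels, a QTL and factor-structured phenotypes with known truth.

# Factor phenotypes

Raw phenotypes are first residualized by ordinary least squares on clinical
covariates (age, sex, BMI, smoking by default; a von Willebrand factor column
can be added per phenotype for shear-dependent platelet-function tests, via
`extra_covariates`). Three phenotype groups are supported: `pre` (baseline),
`post` (on treatment), and `post_adjusted_for_pre`, in which each
post-treatment phenotype additionally gets its matching pre-treatment value in
the adjustment design. The last group is the "treatment responsiveness"
phenotype: the residual of post on pre. We chose plain residualization as the
reading of "post adjusted for pre" because it is the standard way to define a
response phenotype in a regression framework, and it makes the response
exactly orthogonal to the baseline in-sample.

Residuals are Z-scored (sample SD, $n-1$) and decomposed by eigendecomposition
of the correlation matrix. Components with eigenvalue $> 1$ (Kaiser rule) are
retained — the retained count is data-driven, never forced — and rotated by
orthogonal varimax with Kaiser row normalization (the default of the major
statistical packages; switchable via `kaiser = FALSE`). The rotation
is delegated to `stats::varimax` with a convergence tolerance of `1e-8`; the
test suite checks its optimum against a brute-force grid over the rotation
angle. Factor scores use the regression method
($S = Z R^{-1} \Lambda$); whether to use regression or Bartlett scores is a
genuinely open choice — regression scores were chosen because they are the
common default and are well defined even with modest $n$; with orthogonal
rotations their sample covariance is near-diagonal, which the tests verify.
Components are ordered by post-rotation variance explained (a deterministic
tie-break) and labeled by the phenotypes with $|$loading$| > 0.4$.

Degenerate inputs: a zero-variance phenotype stops `zscore` with an error; a
correlation matrix with no eigenvalue above 1 (truly independent phenotypes)
stops `pca_varimax` with "no components retained" rather than fabricating a
factor.

# Multipoint IBD and the Haseman–Elston scan

For each full-sib pair, allele sharing identical by descent (IBD) follows a
hidden Markov model along the Haldane map
($\theta = (1 - e^{-2d/100})/2$ for $d$ in cM, no interference). Each parental
meiosis pair defines a two-state sharing chain with flip probability
$\psi = 2\theta(1-\theta)$; the IBD count is the sum of the two indicators,
with stationary prior $(\tfrac14, \tfrac12, \tfrac14)$. The implementation
runs the exact **four-state product chain** of the two parents rather than a
collapsed three-state chain: with typed parents, sharing the maternal versus
the paternal meiosis produces different genotype likelihoods, so only the
product chain is exact. Emissions use population-frequency formulas when both
parents are untyped, and exhaustive transmission enumeration (untyped parents
marginalized over Hardy–Weinberg genotype probabilities) otherwise; allele
frequencies are always the founder-weighted estimates, with no EM
re-estimation. A missing sib genotype is marginalized — equivalent to a flat
emission only when both sibs are missing. Forward–backward posteriors are
evaluated at every marker and on a 1 cM grid; `pihat = p1/2 + p2`. The test
suite proves the forward–backward posteriors equal brute-force enumeration
over all per-parent sharing paths on maps of up to 5 markers to `1e-10`, and
that posteriors are invariant to reversing the map.

The linkage statistic is the classical Haseman–Elston regression: the squared
factor-score difference of each sib pair regressed on `pihat`, with a
one-sided test of a negative slope ($p = P(T_{n-2} \le t)$). All pairs from
larger sibships enter (a sibship of $k$ contributes $\binom k2$ pairs); the
induced correlation between pairs is ignored, as in the original method — a
documented limitation, acceptable here because sibships are small. Positions
with $\hat\beta \ge 0$ report LOD 0. LOD and pointwise p are linked by the
one-sided mixture convention $p = \tfrac12 P(\chi^2_1 > 2\ln(10)\,\mathrm{LOD})$,
inverted in closed form via the normal quantile (the closed form is exact, so
no root-finding is needed; round-trip error is below `1e-10` across
LOD 0–10). Signals are classified by the genome-wide thresholds
$p < 7.4\times10^{-4}$ (suggestive), $2\times10^{-5}$ (significant) and
$3\times10^{-7}$ (highly significant), each a strict inequality. The scan
grid is every 1 cM plus all marker positions; whether the original software
evaluated between-marker positions is not documented, so the grid density is
an implementation choice exposed as `grid_step`.

# Family-clustered association

Association of a factor with each biallelic SNP uses additive dosage coding
(count of the minor allele by default) in the model
$y = \mu + \beta\,\mathrm{dosage} + b_{\mathrm{family}} + \varepsilon$, with a
family random intercept — i.e. exchangeable correlation between all members
of a family. The fit is maximum likelihood with the fixed effects and residual
variance profiled out and a one-dimensional optimization over the
family-to-residual variance ratio; per-family generalized least squares uses
the closed-form Woodbury inverse, so each SNP costs a handful of vector
operations per family. ML rather than REML keeps the profiled objective simple
and testable; at hundreds of families the difference is immaterial for a
single-dosage fixed effect. The Wald test of $\beta = 0$ uses the
**cluster-robust sandwich variance** with families as clusters (the
"empirical" variance option of classical mixed-model software) against the
standard normal. A variance ratio estimated at the zero boundary is truncated
at zero and flagged; there the fit reduces *exactly* to ordinary least
squares, which the tests assert to `1e-10`, and the suite also cross-checks
$\hat\beta$, variance components and log-likelihood against `lme4::lmer`
(ML) on family-correlated data. Monomorphic SNPs are skipped with a warning;
missing dosages are casewise-deleted per SNP. Marker QC flags (MAF $< 0.02$,
founder-only Hardy–Weinberg $\chi^2_1$ p $< 10^{-6}$, no continuity
correction) travel with the records but never remove a marker.

# Linkage-weighted prioritization

The sparse linkage panel and the dense SNP panel live on different scales
(cM vs bp), so each STR is first **anchored to a physical coordinate** by
piecewise-linear cM$\to$bp interpolation between anchor markers carrying both
scales; STRs outside the anchored range are linearly extrapolated from the
terminal interval and flagged. "The midpoint of the STR" in the source
description is ambiguous (midpoint of flanking SNP positions? of the repeat
tract?); genetic-position interpolation was chosen because it uses all the
map information and is exact at anchor nodes. Each STR's one-sided linkage p
becomes $z = \Phi^{-1}(1-p)$, the z-trace is linearly interpolated along
physical position to every SNP (terminal values held beyond the outermost
STRs; a chromosome without STRs gets a zero trace and a warning), and weights
are

$$w_i = \Phi(z_i) \Big/ \overline{\Phi(z)}$$

— positive, mean exactly one, reducing to all-unit weights on a flat trace.
The exact weight functional used by the original weighted-FDR analysis is not
printed beyond "derived from the standard normal cumulative distribution";
this choice is isolated behind `weights_from_trace` so an alternative (e.g.
an exponential weight family) is a one-function change. Weighted p-values
$p_i / w_i$ are capped at 1, zero p-values floored at machine epsilon, and
converted to q-values with $\hat\pi_0 = \min(1, \#\{p > \lambda\}/(m(1-\lambda)))$
at fixed $\lambda = 0.5$ (the robust single-$\lambda$ estimator; the spline
variant is out of scope). With $\pi_0 = 1$ the q-values are exactly
Benjamini–Hochberg, which the tests assert against a hand-rolled oracle. Two
significance views are reported per SNP: the strict genome-wide Bonferroni
flag ($p < 10^{-8}$, unweighted) and the weighted-FDR flag ($q \le 0.05$),
plus a **region-specific Bonferroni screen**: around every STR with linkage
$p < 7.4\times10^{-4}$, SNPs within $\pm 5$ Mb are tested at $0.05/n$ with
$n$ the SNPs in the window (strict inequality; overlapping windows are
deduplicated in the summary).

Whether the original analysis pooled factors or ran Storey's procedure per
factor is not stated; `sibscan` runs it per factor, matching the per-factor
association scans.

# The simulator and what passing tests mean

`sim_config()`/`gene_drop()`/`simulate_phenotypes()` generate the study
structure end to end: nuclear families (two typed parents, configurable
sibship sizes), two population strata by default with stratum-specific allele
frequencies (STRs draw 4–8 alleles from a flat Dirichlet; SNP minor-allele
frequencies are uniform on 0.05–0.5), an STR panel at 8 cM average spacing, a
dense SNP panel (default one per 500 kb — a computationally honest stand-in
for a million-SNP array; array-scale density changes only multiplicity, not
the per-SNP model), and genotype missingness at 0.35%. Founder haplotypes are
dropped through the pedigree by Markov recombination on the Haldane map, so
genotypes are Mendelian-consistent by construction and true IBD is recorded
at every marker. The QTL is realized as a member of the SNP panel (with a
configurable MAF, default 0.3): population linkage disequilibrium is
deliberately *not* modeled, so a non-genotyped causal variant would be
undetectable by association by construction — placing the causal variant on
the panel is the only configuration in which association power is meaningful.
When no SNP panel is requested, a latent biallelic locus (class `QTL`) is
dropped instead, excluded from IBD estimation, QC and association.

Latent factors are built from the standardized QTL dosage (response factors
only, default $h^2_{QTL}$ 0.3 on factor 1), a polygenic component with
kinship-proportional covariance (founders independent, children = midparent +
Mendelian deviation; default 0.2), a family-shared environmental effect
(default 0.1) and individual noise, with *population* variance fractions as
configured. Raw phenotypes are a 3-block loading matrix (loading 0.8, twelve
phenotypes) times the factors, plus covariate effects and measurement noise;
`post = pre + response`, so residualizing post on pre recovers the response
factors. Default family counts (250 per stratum, sibships of 2) mirror the
motivating study's scale of a few hundred sib pairs per stratum; validation
simulations use 500 pairs.

What the simulator does **not** emulate — and hence what green tests do not
establish about real data: population LD and association test multiplicity at
array scale, allele-frequency misspecification, genotyping error (Mendelian
checks are exercised by constructed fixtures, not by simulated error),
ascertainment through an affected proband, non-normal phenotype
distributions, and half-sib or multi-generation IBD configurations (the IBD
model is exact for full sib pairs only, matching the sib-pair design).

# Numerical choices and problem sizes

* Convergence: varimax `1e-8`; the variance-ratio optimization uses Brent's
  method on the log scale with an explicit boundary comparison at zero.
* Floors and caps: p-values floored at machine epsilon before
  $\Phi^{-1}$/division; weighted p capped at 1; $\hat\pi_0$ capped at 1.
* Determinism: a single integer seed governs a whole pipeline run; reruns are
  byte-identical, which the tests assert on the emitted CSVs.
* Validation problem sizes (chosen once as study-scale): 500 sib pairs on a
  100 cM chromosome with 13 STRs for calibration and power; 1000 null
  phenotype replicates for the uniformity and type-I checks; 20 replicates
  for power fractions; $m = 10^4 \times 100$ replicates for FDR control;
  brute-force IBD oracles on maps of 2–5 markers.

A note on power: with 500 sib pairs, perfect marker information and
$h^2_{QTL} = 0.3$ under the default polygenic/shared background, the
Haseman–Elston noncentrality at the QTL is about 2.6 against a one-sided
suggestive threshold of $z = 3.18$ — pointwise power near 25% at best, and
near 10% with estimated factor scores and multipoint sharing. Sib-pair
regression simply needs thousands of pairs for moderate QTL effects; the
package's power simulation reports the realized fraction rather than
asserting more than the design can deliver. The identical pipeline detects an
$h^2 = 0.6$ QTL essentially always at this sample size, which is the relevant
positive control that the machinery, as opposed to the design, is sound.

# Worked example

```{r, eval = FALSE}
library(sibscan)

scfg <- sim_config(n_families = 150, n_strata = 1,
                   chromosomes = data.frame(length_cm = 100, length_mb = 100),
                   snp_spacing_kb = 1000,
                   qtl = list(chrom = 1, cm = 50, h2 = 0.5, maf = 0.3,
                              factor = 1))
cfg <- run_config(sim = scfg, group = "post_adjusted_for_pre",
                  seed = 17, out_dir = "results")
res <- run_pipeline(cfg)

res$stratum1$factors          # retained components and their labels
linkage_peaks(res$stratum1$scan)
head(res$stratum1$prioritized[[1]])
```

The run directory contains one CSV per stage (marker QC, loadings, scores,
IBD traces, linkage scan, association, prioritized results) and a
`manifest.json` with the config hash, seed and per-stage row counts. The
association and prioritization stages run only for factors with at least one
position below the suggestive threshold, mirroring the design of following up
linkage with association.
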