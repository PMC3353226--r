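---
title: "Estimating SNP effects on quantitative traits from pooled DNA"
author: "poolfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SNP effects on quantitative traits from pooled DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolfx)
```

# The estimation problem

DNA pooling replaces per-individual genotypes with per-pool allele-frequency
estimates.  For a quantitative trait the quantity of interest is still the
per-allele effect α in trait units, but the standard least-squares
regression of phenotype on genotype is unavailable — and, under selective
pooling designs where pools are built from phenotype ranks, the
phenotype-on-genotype direction is biased anyway.  The estimator implemented
here reverses the regression: it models the *allele content* of a pool as a
function of the pool's mean phenotype.

## Model

Assume a biallelic SNP with additive genotype effects (−α, 0, +α) and a
Gaussian residual with diploid variance σ²ₑ.  Each individual contributes
two haploid DNA copies and, under additivity, half its phenotype per copy;
haploid phenotypes then follow a two-component normal mixture, and the
probability π that a haploid copy carries the increasing allele is logistic
in the haploid phenotype Y:

$$\log\frac{\pi}{1-\pi} = g + bY, \qquad b = \frac{2\alpha}{\sigma_e^2}.$$

Both g and b are estimable by a standard binomial GLM with logit link
(`fit_binomial_logit()`, built on `stats::glm.fit`).  The observations are
per-pool allele counts — estimated frequency × 2n haploid copies for a pool
of n individuals — with one half of the pool mean phenotype as regressor and
optional covariates (contemporary-group indicators, stratification
eigenvectors) in the linear predictor.  Using the variance decomposition
σ² = σ²ₑ + 2p(1−p)α², the fitted slope converts back to trait units:

$$\alpha = \frac{-1+\sqrt{1+2p(1-p)\,b^2\sigma^2}}{2p(1-p)\,b},$$

implemented in the cancellation-free form
α = bσ² / (1 + √(1 + 2p(1−p)b²σ²)), which is continuous through b = 0 (its
value there is the series limit bσ²/2) and exact to machine precision over
the whole parameter range — the package's round-trip property test inverts
the forward map to 10⁻¹² .

## Numerical and inferential choices

* **Counts are haploid.**  Binomial totals are 2n copies per pool of n
  individuals.  An `"individuals"` scale (totals = n) is provided as an
  option; it leaves b and α unchanged but halves the effective binomial
  information, deflating every −log₁₀ p-value roughly twofold.  The haploid
  default is the scale on which the mixture model is derived, and it is the
  scale that reproduces the published significance benchmarks for this
  estimator (see the acceptance script), including the un-pooled
  logistic-vs-least-squares MLP slope of ≈ 0.92.
* **Fractional counts.**  Frequency × 2n is rarely integral; the GLM
  machinery accepts real-valued successes (binomial quasi-likelihood) and
  the usual non-integer-count warning is deliberately muffled.
* **Significance** is the Wald z-test on b, matching `summary.glm`; a
  likelihood-ratio alternative is available (`test = "lrt"`).  P-values are
  handled on the log scale throughout, and MLP = −log₁₀ p is capped at 300.
* **Convergence.**  IRLS runs at most 100 iterations with relative deviance
  tolerance 10⁻⁸.  Non-convergence and quasi-separation (fitted
  probabilities numerically 0/1) set `converged = FALSE` instead of raising,
  so genome scans continue past degenerate SNPs; fits where every pool is
  fixed for one allele return a flagged estimate.
* **p̂ and σ².**  The allele frequency entering the back-transformation is
  the pool-size-weighted mean pool frequency.  σ² is the sample variance of
  the individual phenotypes — after removing contemporary-group effects
  when the model fits them (concurrently or by pre-adjustment).  When only
  pool-level data exist, σ² must be supplied explicitly.
* **Covariate coding.**  Contemporary groups are treatment-coded with the
  first level as reference; eigenvectors enter as raw real covariates and
  are never nested within group.

# Pooling designs

`assign_pools_by_rank()` sorts individuals by phenotype (stable ties) within
each stratum — a contemporary group, or the whole cohort — and cuts the
ranking into contiguous blocks whose sizes differ by at most one, lower
ranks taking the extra individual.  With within-group pooling, per-group
pool counts are apportioned proportionally to group size by largest
remainder, with every group guaranteed one pool; 940 individuals in 29
groups at 134 pools yields pools of six to eight.

Pool frequencies are exact in-silico frequencies (sum of dosages / 2n);
`perturb_frequencies()` adds i.i.d. Gaussian measurement error, clamped to
[0, 1], emulating assay noise.  Per-SNP filters drop contemporary groups
whose size-weighted minor allele frequency falls below 0.01 — effectively
groups fixed for one allele, which would otherwise confound group and SNP
effects.

# Population stratification

A genomic correlation matrix for pools is built from allele frequencies by
VanRaden's first construction with pool frequencies in place of dosages:
M = 2f − 2p̄ (p̄ size-weighted, from the pools themselves), G = MMᵀ /
(2Σp̄(1−p̄)), then standardised to a correlation matrix.  With singleton
pools this reduces exactly to the individual-genotype construction.
Pool-size-dependent shrinkage of the frequency variance is not applied —
there is no principled single formula for mixed pool sizes, and the
correlation standardisation absorbs most of the scale differences; the
choice matters only for the relative weighting of pools of unequal size.
The first five eigenvectors (fixed sign: largest-magnitude loading
positive) are fitted as covariates regardless of significance, mirroring
common GWAS practice of a fixed PC count.

Two cautions discovered during development are worth stating.  First, the
"two identical pools" intuition for the correlation matrix is degenerate:
with exactly two pools, centring by the weighted mean forces the two rows
of M to be proportional with opposite sign, so correlations are ±1 or 0/0
by construction; identity of frequency vectors is only a meaningful signal
inside a larger pool set.  Second, eigenvector correction needs a dense
SNP panel: with only a few hundred SNPs, each SNP contributes enough to the
correlation matrix that the eigenvectors become partially collinear with
that SNP's own pool frequencies and absorb real signal.  The package's
structural tests therefore use panels of 1000+ SNPs.

# The simulation study

`run_simulation_study()` reproduces the single-SNP benchmark design: 3000
unrelated individuals per replicate, allele frequency p ~ U(0.01, 0.99),
per-allele effect α ~ U(0, 0.5) trait units, phenotype = dosage·α + N(0, 1);
1000 replicates (200 in the reduced test mode); pools of 2ᵏ over the whole
cohort; optional frequency error of SD 0.05.  Replicate estimates from
pooled logistic regression are compared with individual least squares by
regressing one on the other across replicates (with intercept), reporting
R² and slope, overall and within the low-significance subset
(least-squares MLP < 5, i.e. p > 10⁻⁵ — the subset where it actually
matters whether a signal is real).  Each replicate runs on its own RNG
substream derived from the master seed, so any replicate is reproducible
in isolation.

Expected behaviour, verified by the acceptance tests: at 64 pools the
pooled analysis is practically indistinguishable from genotyping all 3000
individuals (R² ≈ 0.998 for α on the low-significance subset); R² decays
as pools decrease (≈ 0.98 at 16 pools, ≈ 0.90 at 4) while the α slope
stays near one; the un-pooled logistic α is conservatively scaled against
least squares (slope ≈ 0.967), so the two methods converge to *different*
estimands; and frequency measurement error degrades agreement
monotonically as pools shrink.  One caveat: the α R² in the
measurement-error arm is sensitive to rare replicates with extreme allele
frequency, where clamped noise produces outlying α estimates; a squared
correlation over 1000 replicates can move by several points on the
strength of a handful of such replicates, whereas the MLP comparisons are
stable.

# The synthetic stratified cohort

Since the original stratified livestock data are not public, the package
ships a generator emulating their structure: two breeds diverged under a
Balding–Nichols model (breed frequencies Beta-distributed around a
U(0.05, 0.95) ancestral frequency at Fst = 0.1), 940 individuals in 29
near-equal contemporary groups nested within breed (the real groups were
unequal, 16–76; near-equal sizes are used because the actual sizes are not
published), 5000 SNPs of which 50 carry N(0, 1)-drawn additive effects,
group effects of SD 0.5 phenotypic standard deviations, and a
high-heritability trait (h² = 0.65, the published estimate for the
emulated trait).  Effects are rescaled on the realised genotypes and the
noise is orthogonalised against genetic values within groups, so the
realised within-group heritability equals the target exactly in every
cohort instance — convenient for tests that do variance accounting.

`compare_pooling_strategies()` mirrors the design comparisons: within-group
pooling with concurrent group + eigenvector fitting; pre-adjusted
phenotypes with within-group or cross-group pooling; and one random
individual assayed per pool.  Each is scored by the R² of its per-SNP α
and MLP against the individual least-squares reference (concurrent groups,
eigenvectors, group-MAF exclusions), per population-MAF stratum.

**What the synthetic cohort does and does not show.**  Pooling within
groups at 134 pools recovers the reference with R²(α) ≈ 0.67–0.69, closely
matching the level reported for the real data at that design, and pooled
assays dominate one-individual-per-pool assays by a wide margin (median
R²(α) ≈ 0.67 vs ≈ 0.14 over five seeds).  However, the real-data finding
that within-group pooling beats cross-group pooling after pre-adjustment
does *not* reproduce here: with two cleanly diverged populations, a single
eigenvector of the pool correlation matrix captures each pool's breed
composition almost completely, so the five-eigenvector correction fully
rescues cross-group pools (median R²(α) ≈ 0.78).  The real comparison was
driven by one breed being a multi-founder composite — high-dimensional
admixture that a fixed low eigenvector count cannot absorb and that a
two-population drift model cannot represent.  The corresponding acceptance
check is accordingly expected to fail on this generator, and the package
documents rather than hides that limitation.  Likewise, LD structure and
pedigree relationships are absent, so synthetic results are pattern-level
only.

# Problem sizes

Defaults are the study conditions above.  The test suite scales down where
statistically safe: the simulation benchmarks run at 200 replicates (the α
and MLP comparisons at 64 pools have Monte-Carlo SDs well under the
tolerances used), structural tests use cohorts of 200–940 individuals and
panels of 120–5000 SNPs, and the strategy comparison runs the full default
cohort over five seeds.  `scripts/acceptance.R` always runs the full
1000-replicate protocol.

# Limitations

* Only additive haploid allele effects are estimable from pools — no
  dominance or parent-of-origin models.
* Biallelic SNPs only; haplotype frequencies are out of scope.
* Measurement error beyond additive Gaussian noise on frequencies (unequal
  DNA contributions, assay-specific biases) is not modelled.
* The correlation matrix is used only through its leading eigenvectors;
  fitting it as a random effect is not implemented.
* Missing genotypes are an input error: pools built in silico have none,
  and imputation belongs upstream.
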