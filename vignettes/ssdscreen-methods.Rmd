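---
title: "Methods: screening gene-family size against sexual size dimorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening gene-family size against sexual size dimorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ssdscreen` links a continuous, sexually dimorphic phenotype — the log2
ratio of adult male to female body mass (SSD) — to gene-family size
evolution across a mammalian phylogeny. This vignette is the package's
account of the statistical model behind each stage, the tunable
parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## 1. Trait model

SSD is defined as `log2(male_mass / female_mass)`; mean body mass is
`(male + female)/2` and is log10-transformed before use as a covariate.
The log2 base for SSD makes a value of 1 mean "males twice as heavy";
the scale is symmetric around 0 under sex swap, which the test suite
asserts exactly. Relative brain size is the residual of an ordinary
least-squares fit of `log10(brain)` on `log10(body)`: the deviation of a
species' brain from the allometric expectation. Residuals sum to zero by
construction and are invariant to rescaling body mass, so unit choices
(g vs kg) cannot leak into downstream screens.

Rensch's rule — dimorphism increasing with size where males are the
larger sex — is tested by major-axis (MA) regression of `log10(male)` on
`log10(female)` mass. MA treats both axes symmetrically (both masses are
measured with error; neither is a "predictor"), and the rule corresponds
to a slope above 1. The slope is the first principal axis of the 2×2
covariance matrix; the test of H0: slope = b rotates the data into the
hypothesized fitted axis `v = x + b·y` and residual axis `u = y − b·x`,
which are uncorrelated under H0, and refers
`F = r_uv²(n−2)/(1−r_uv²)` to F(1, n−2). When the data sit exactly on
the hypothesized axis, `var(u) = 0` and p is 1 by construction. The MA
test is deliberately not phylogenetically corrected: it describes the
observed species scatter. As a complement, `test_rensch` also reports
`r_assoc`, the correlation between SSD and log10 mean mass (Pearson by
default, Spearman by config), since the SSD-size association can be
summarized either through the MA fit or directly; both are reported so
either reading can be checked.

## 2. Family filtering

Three rules, all applied to the species set that actually enters the
regression (i.e. after intersecting tree, traits and counts):

* **Prevalence**: count > 0 in at least `ceiling(0.80 · n_species)`
  species. "At least 80%" is read as a lower bound, hence the ceiling;
  with 124 species the threshold is exactly 100. This removes
  lineage-specific families whose zeros would otherwise dominate.
* **Maximum count**: at least 3 genes in at least one species, avoiding
  pure presence/absence contrasts.
* **Variance**: some variation across species, since a regression cannot
  explain variance that does not exist.

Filtering is idempotent, and the report records per-family provenance
(which rules failed), so the filter is auditable. Whether prevalence
should be computed before or after species pruning is ambiguous in
principle; computing it after pruning keeps the filter consistent with
the regression's species set, which is the property that matters for the
fitted model.

## 3. The PGLS screen

Each family's count vector is modelled as Gaussian with a linear trait
effect and phylogenetically correlated errors:

y = Xβ + ε, ε ~ N(0, σ²C), with `C_ij` the depth of the most recent
common ancestor of species i and j (the Brownian-motion covariance) and
`X = [1, SSD, log10 mass]` or `[1, SSD, relative brain size]`.
Numerically the fit whitens by the Cholesky factor `C = RᵀR` and runs
OLS on `R⁻ᵀy, R⁻ᵀX`; this is algebraically the generalized
normal-equations solution but avoids forming `C⁻¹`, and the whole screen
is one vectorized least-squares pass over all families. Tests verify the
whitened path against an explicit dense-inverse oracle at 1e-8 and
against `nlme::gls` with a Brownian correlation structure on an
ultrametric tree.

Choices worth making explicit:

* **Brownian only.** No Pagel's λ or OU estimation; the error structure
  is the plain Brownian covariance. This keeps the per-family model a
  single GLS solve and matches the screen's stated assumptions.
* **Effect size.** `r = t/√(t² + df)` is a strictly monotone,
  sign-preserving transform of t, so ranking or thresholding on |r| at
  fixed df is equivalent to doing so on |t|; it is reported because a
  correlation scale is comparable across screens with equal df.
* **Classification gate.** Expanding/contracting calls gate on
  BH-adjusted p < α (α = 0.05), the conservative reading; a
  `use_raw_p` switch reproduces the raw-p reading. The |r| > 0.3
  threshold is a secondary "strong" label rather than part of the gate,
  because a hard 0.3 gate is inconsistent with admitting effects down to
  |r| ≈ 0.24 at n = 124 — both behaviours are reproducible from config.
* **Per-predictor BH.** p-values are adjusted across families separately
  for each predictor; the two predictors answer different questions and
  pooling them would couple their error budgets.
* **Missing traits.** Species lacking a predictor (e.g. brain mass) are
  dropped for the whole screen, not per family, so every family in one
  screen shares a common n and df. This mirrors running the SSD + mass
  model on the full species set and the SSD + relative-brain model on
  the subset with brain data.
* **Degenerate fits** (zero residual variance) are flagged and reported
  as `ns` with `NA` statistics; they never produce divisions by zero or
  spurious calls.
* **Counts as Gaussian.** Family sizes are small nonnegative integers,
  and the Gaussian GLS is an approximation. The screen deliberately does
  not implement count likelihoods (phylogenetic Poisson, birth-death
  gain/loss models); the synthetic generator's Poisson switch exists to
  probe robustness to this approximation.

## 4. GO enrichment

A term is linked to a family if any member gene in any species carries
it. Terms annotated to fewer than `small_go_min = 50` families are
pooled into a single `small_GO` pseudo-term that is kept in the map
(edges conserved) but excluded from testing and from the BH family — the
strictness of "fewer than 50" means a 50-family term is retained.

Enrichment of a focal set compares the observed count of focal families
per term against `n_resamples = 10000` draws of size |focal| taken
uniformly **without replacement** from the background. Without
replacement is the natural reading of "equally sized random samples from
the background set" and makes the per-term null exactly hypergeometric —
which the tests exploit: the null mean and SD must match the closed-form
hypergeometric moments within Monte-Carlo error. `Z` is computed from
the null mean/SD, p is the upper normal tail (enrichment; a two-sided
config option exists for depletion scans), and BH runs across testable
terms only. Degenerate terms (null SD 0, e.g. a term carried by every
family) fall back to the add-one empirical tail and are flagged.

The background is the set of families that entered the screen, not all
families in the genome: the focal set was selected from that universe,
and enrichment must condition on the selection universe or it will
rediscover the filter instead of biology.

## 5. Expression statistics

* **Brain rank.** For each gene, the number of non-brain tissues with
  replicate-averaged expression strictly greater than the brain's. Ties
  do not increment the rank ("higher than" is strict). The statistic
  depends only on within-gene ordering, hence is invariant to any
  monotone transform of expression — so whether values are raw or
  log-scaled cannot change it. Significance of a gene set's mean rank
  comes from 10,000 bootstrap sets of equal size drawn with replacement
  from all genes with a brain value; p is the add-one lower-tail
  estimator (low rank = brain-biased), which can never be exactly 0.
* **Temporal trajectories.** Stage means of `log2(x+1)` expression are
  computed per brain structure group (cortex, subcortex, cerebellum:
  fixed region-code sets exposed by `brain_structure_groups()`),
  averaging regions within gene before genes, then an OLS slope against
  the stage axis. The axis is ordinal stage position by default, because
  published slopes of this kind rarely state their time units; numeric
  age is available via `use_age = TRUE`. No slope value is asserted
  against external figures for exactly that reason.
* **Sex bias.** Per gene, `log2((female mean + 1)/(male mean + 1))` over
  matched (region, stage) pairs within a phase (prenatal and adult are
  disjoint by construction and analysed separately); the +1 keeps zero
  expression finite, consistent with the `log2(x+1)` transform. The
  per-gene vector is tested against 0 by a two-sided one-sample Wilcoxon
  signed-rank test (`stats::wilcox.test`: exact for small samples,
  normal approximation with continuity correction otherwise), BH across
  genes. Sex-mean ratios per pair — rather than per-sample pairing — are
  used because expression tables aggregated to (region, stage, sex)
  means are the common denominator of public brain atlases.

## 6. What the generators emulate — and what they do not

The synthetic-data module exists so that every downstream stage can be
validated by parameter recovery. Its defaults are the package's fixed
study conditions:

* **Tree**: pure-birth (Yule) with unit birth rate, rescaled to root
  depth 1 — the simplest ultrametric branching process, standing in for
  a time-calibrated phylogeny. 124 tips in the reference runs, matching
  a realistic mammalian study panel. No extinction, no gene-tree
  discordance.
* **Traits**: correlated bivariate Brownian motion for (SSD, log10
  mass), with `sigma_ssd = 0.4`, `sigma_bm = 1.2`, `rho = 0.4`, roots
  0.3 and 3.5. On a depth-1 tree these give tip spreads comparable to
  real mammal panels: SSD mostly within −0.5…1.5 and body masses
  spanning several orders of magnitude, with a moderate positive
  SSD-size coupling. Male/female masses are back-derived by inverting
  the two defining identities, so the phenotype stage reproduces the
  simulated SSD exactly (a round-trip the tests assert at 1e-12). Note
  that a single Brownian realization on one tree has few effective
  degrees of freedom, so the realized SSD-mass correlation varies widely
  around rho between seeds — a property of the process, not a bug.
* **Counts**: latent `a_j + b_j·SSD + u`, `u ~ N(0, noise_sigma²·C)`
  with `noise_sigma = 1`, baselines Unif(4, 12), rounded and clipped at
  0. The rounded-Gaussian choice matches the fitted model's assumptions,
  so parameter recovery measures the estimator, not generator mismatch;
  a Poisson switch exists for robustness checks. Rounding does add
  discretization noise that the Brownian covariance does not describe —
  after whitening it attenuates realized effect sizes below the latent
  target (observed mean |r| ≈ 0.37 when calibrating to 0.5) and leaves
  null p-values only approximately uniform. `calibrate_effect_scale`
  computes the latent `b` for a target effect size through the exact GLS
  standard error of the design, so "true r" is defined pre-rounding.
* **GO**: flat term sets (no DAG, no ancestor propagation) with one
  planted term whose overlap with a designated focal set is controlled;
  gene-level annotations are emitted through 1–3 carrier genes per
  family so the gene-to-family collapse is exercised.
* **Expression**: i.i.d. Gaussian log2 baselines (per-gene mean
  N(5, 1), cell noise SD 1) with a +3 log2 brain shift for planted
  genes and an additive female log2 fold change; values are exported as
  `2^L − 1` so the pipeline's `log2(x+1)` recovers the simulated scale
  exactly. Real expression data have correlated tissues, heavy tails,
  batch structure and missingness, none of which are modelled — passing
  tests demonstrate correctness of the statistics under their stated
  assumptions, not robustness to those real-data pathologies.

## 7. Problem sizes and numerical choices

The reference analyses (test suite and `scripts/acceptance.R`) use 124
species, 1000 families (100 planted at latent effect size 0.5), 500
background families with a 30-family planted GO term against a 50-family
focal set at 10,000 resamples, 500 genes × 20 tissues for the rank
statistic at 10,000 bootstraps, and 120 genes × 5 regions × 8 stages for
sex bias. These sizes keep a full run in the low seconds while leaving
Monte-Carlo error well inside the asserted tolerances (e.g. the
hypergeometric-moment checks use 3 standard errors at B = 10,000).

Numerical specifics: covariance solves use Cholesky factorizations
(failure to factor is reported as non-positive-definiteness rather than
propagating NaNs); rank deficiency of the whitened design is caught via
a reciprocal-condition-number check at 1e-12; BH adjustment delegates to
`stats::p.adjust` and is property-tested against a literal step-up
transcription; all RNG flows through explicit seeds and
`withr::with_seed`, so library calls never disturb the caller's RNG
stream; and every result table is written at 6 significant digits,
making repeated runs byte-identical.

## 8. Known limitations

* The Gaussian PGLS treats integer counts as continuous; families with
  very low counts and many zeros are better served by count models that
  are deliberately out of scope here.
* Exact-name species matching (after whitespace trimming and
  space-to-underscore normalization) between tree and tables; no fuzzy
  synonym resolution — mismatches are logged and dropped.
* Flat GO annotation sets; no term-ancestor inheritance.
* The MA-based Rensch test is not phylogenetically corrected, by design.
* Temporal slopes are reported in per-stage (ordinal) units unless ages
  are supplied; they are not comparable across data sets with different
  stage grids.
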