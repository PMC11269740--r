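# ssdscreen

Comparative-genomics screening of gene-family size evolution against
sexual size dimorphism (SSD) in mammals.

Across mammals, males and females often differ in body mass, and the
degree of that dimorphism varies enormously between lineages. `ssdscreen`
implements a reusable pipeline for asking which gene families have
expanded or contracted in concert with SSD across a phylogeny, and what
those families do: trait derivation and Rensch's-rule testing, gene-family
filtering, a per-family phylogenetic generalized least squares (PGLS)
screen, resampling-based GO-term enrichment, and human brain-expression
statistics. A synthetic-data module generates phylogenies, traits, family
counts, GO annotations and expression tables with known ground truth, so
every stage of the pipeline is testable end to end without any external
download.

It is aimed at researchers in phylogenetic comparative methods and
molecular evolution who have (or can simulate) a rooted time tree, a
families-by-species gene-count matrix, per-species male/female body
masses, gene-level GO annotations, and tissue expression tables.

## The statistics at the core

**Traits.** SSD is the log2 ratio of average adult male to average adult
female body mass, `ssd = log2(M/F)` (positive = males larger); body mass
is log10-transformed; relative brain size is the residual of an OLS fit
of `log10(brain)` on `log10(body)`. Rensch's rule (SSD increasing with
size) is tested by major-axis regression of `log10(M)` on `log10(F)`:
the first principal-axis slope

    slope = (s_yy − s_xx + sqrt((s_yy − s_xx)² + 4 s_xy²)) / (2 s_xy)

with a rotation test of H0: slope = 1.

**Screen.** Families are kept if present (count > 0) in ≥ 80% of species,
reach ≥ 3 genes in some species, and vary across species. Each family's
count vector y is then fit by GLS,

    y = X β + ε,   ε ~ N(0, σ² C),   C_ij = depth of MRCA(i, j),

with design `X = [1, SSD, log10 mass]` (or `[1, SSD, relative brain
size]`) and C the Brownian-motion covariance of the tree, solved by
Cholesky whitening. Per predictor, the t statistic is converted to a
correlation-scale effect size `r = t / sqrt(t² + df)`, p-values are
Benjamini–Hochberg adjusted across families, and families are classified
as *expanding* (significant, r > 0) or *contracting* (significant,
r < 0), with a secondary *strong* label at |r| > 0.3.

**Enrichment.** GO terms are linked to a family whenever any member gene
carries the term; terms with fewer than 50 families are pooled into an
excluded "small_GO" category. A focal set (e.g. expanding families) is
compared against 10,000 equally sized random draws from the background:
`Z = (x_obs − null_mean)/null_sd`, upper-tail p, BH-adjusted.

**Expression.** The brain rank of a gene is the number of non-brain
tissues expressed strictly higher than the brain (0 = brain is top); a
gene set's mean rank gets a bootstrap p from 10,000 resampled sets.
Temporal trajectories are OLS slopes of stage-mean `log2(x+1)` expression
for cortex/subcortex/cerebellum; sex bias is the per-gene
`log2((female+1)/(male+1))` fold-change vector over matched
(region, stage) pairs, tested by a one-sample Wilcoxon signed-rank test
with FDR correction.

## Worked example

```r
library(ssdscreen)

tree   <- simulate_tree(124, seed = 1)          # Yule tree, root depth 1
traits <- simulate_traits(tree, seed = 2)       # correlated SSD / mass diffusion
test_rensch(traits)
#> Major-axis regression (n = 124)
#>   slope = 0.9971  intercept = 0.0547  r = 0.9945
#>   H0 slope = 1: p = 0.7626   H0 r = 0: p = 1.567e-121

b  <- calibrate_effect_scale(tree, traits, target_r = 0.5)
fc <- simulate_family_counts(tree, traits, n_families = 1000,
                             frac_assoc = 0.1, effect_scale = b, seed = 4)
filt   <- filter_families(fc$counts)
screen <- screen_families(filt$counts, traits, tree)
head(subset(screen, term == "ssd" & call != "ns"))
#>   family      beta         t        p_adj          r        call strong
#>  OG00234 -2.319162 -7.043447 1.235548e-07 -0.5392409 contracting   TRUE
#>  OG00225  1.923819  6.258926 1.169423e-06  0.4945425   expanding   TRUE
#>  OG00392 -1.907708 -6.299728 1.169423e-06 -0.4969721 contracting   TRUE
```

Here 100 of the 1000 simulated families carry a planted SSD effect
calibrated to a true effect size of |r| = 0.5; the screen recovers 90 of
them (38 expanding + 53 contracting minus one false discovery), every
call with the planted sign. The major-axis slope is consistent with the
simulated isometric expectation (its p against unity is 0.76), and the
near-unity correlation r = 0.9945 reflects how tightly male and female
log masses covary along the tree.

The same pipeline runs from the shell over on-disk Newick/TSV files:

```sh
Rscript inst/scripts/ssdscreen.R simulate --out-dir study --seed 1
Rscript inst/scripts/ssdscreen.R run-all --in-dir study --out-dir results --seed 1
```

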