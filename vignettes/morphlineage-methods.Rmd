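---
title: "Methods: morphological phenotyping of breeding lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological phenotyping of breeding lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated single-cell image analysis of triple-stained yeast (cell wall,
actin, nuclear DNA) summarizes each culture into 501 numeric morphological
traits: sizes, shapes, orientations, localization measures, and — for 220 of
them — coefficients of variation quantifying cell-to-cell variability within
the isogenic culture. Given replicate-level trait tables for a collection of
related strains, a recorded breeding lineage (who was isolated or crossed
from whom, and how), and optionally genotypes, `morphlineage` answers the
questions a breeding program asks of such data:

* How far did each breeding step move a strain in morphology space, and do
  mutagen-assisted isolations move further than spontaneous ones?
* Do hybrids land at the additive mid-parent expectation, or beyond it?
* Which strains have lost cellular buffering (high phenotypic noise), making
  them risky production organisms?
* Do morphological and genetic distances tell the same story?

## The model

### Per-trait GLM normalization

Raw traits live on incommensurable scales, so each trait is first fitted
with a generalized linear model matched to its value domain:

| family class | domain | model | link |
|---|---|---|---|
| `unbounded` | real | gaussian | identity |
| `positive`  | $(0,\infty)$ | gamma | log |
| `proportion`| $[0,1]$ | beta | logit |

The linear predictor contains the strain (and, when cultures span media, an
additive medium term, so medium effects are subtracted from strain
contrasts). The reference strain is the baseline level, and the strain's
**Wald Z** — coefficient over standard error — becomes its normalized
phenotype for that trait. A strain's **Z-profile** over all traits is the
unit of all downstream analysis. In *replicate mode* each replicate is its
own factor level, yielding per-replicate Z-profiles; the reference strain's
own replicates are represented by leave-one-out studentized link-scale
deviations, which are on the same out-of-sample scale as a singleton
replicate's Wald statistic (this calibration matters for the noise envelope
below). Proportion values exactly 0 or 1 are shrunk by $(y(n-1)+0.5)/n$
with $n$ the culture's cell count before beta fitting.

The per-trait density/link assignment of the original protocol is not
published as a table; the three-family menu above is this package's own
fixed assignment by value domain, and a user-supplied catalog can override
the family of any trait. The beta regression is estimated by full maximum
likelihood (BFGS with analytic gradients, observed-information standard
errors); an `mgcv` beta-family fit is used as an independent cross-check in
the test suite. Model choice among candidate designs uses AIC (ties go to
the smaller model); trait screens use the likelihood-ratio or Wald test
with Bonferroni correction. Wald screens use the Student-t reference with
the model's residual degrees of freedom — exact for the gaussian family and
a small-sample approximation otherwise; simulation in the test suite shows
the family-wise error of the Bonferroni screen is held at its nominal
level under this choice, which a standard-normal reference would not
achieve at 16 observations.

### The orthogonal phenotypic space

PCA of the strain-by-trait Z matrix (centered, not rescaled — the Z scale
is already comparable across traits; rescaling is available) gives the
"degenerated" orthogonal space. Distances computed there are not biased by
correlated traits. Each analysis keeps the smallest number of leading
components whose **cumulative contribution ratio (CCR)** reaches a
conventional threshold: 0.90 for distance analyses, 0.60 for clustering.
Components below numerical rank (singular value $< 10^{-10}$ of the
largest) are dropped, and a deterministic sign convention (largest-magnitude
loading positive) makes results platform-stable.

### Lineage distance statistics

The morphological distance between strains $x$ and $y$ is the Euclidean
distance $d(x,y)=\sqrt{\sum_i (x_i-y_i)^2}$ over the retained component
scores. Replicates are never averaged before measuring: with 5 replicates
per strain, a strain pair yields the full $5\times5=25$ distance multiset;
a cross yields $25$ mid-parent points (element-wise means of all parent
replicate pairs) and $5\times25=125$ hybrid-to-midpoint distances, each
summarized by mean and SD. The **cross-distance ratio** divides each
hybrid-to-midpoint distance by the mean parent–parent distance, giving a
scale-free measure of departure from additive expectation with 125 values
per cross; the mean-denominator choice reproduces those combination counts
exactly (a pair-matched denominator is available as an option). Group
location comparisons use the Wilcoxon–Mann–Whitney test, exact when both
groups have at most 20 untied values. Projected cell area converts to
volume by $V=\frac{4}{3\sqrt{\pi}}A^{3/2}$ (spherical-projection
convention; absolute femtoliter values depend on this convention, ratios do
not).

### Phenotypic potential

The robustness score of a replicate is the fraction of the 220 noise traits
whose Z value falls outside the reference strain's two-sided 95% envelope
(mean $\pm 1.96\,$SD of the reference's per-replicate Z). A
reference-calibrated replicate therefore scores near 0.05, and scores grow
toward 1 as cell-to-cell variability escapes the reference envelope. The
published definition of this score is in work not reproduced here, so the
envelope-exceedance fraction is this package's own operationalization; an
alternative mean-|Z| definition is provided and every output records which
definition produced it. Strains are compared against a designated control
strain by Dunnett's many-to-one procedure (common-variance model,
multivariate-t adjusted p-values via `multcomp`, as is standard).

### Clustering and genotype–phenotype comparison

Strains are clustered by average linkage (UPGMA) on $1-R$ dissimilarity,
where $R$ is the Pearson correlation between strain score vectors over the
components at CCR 60%. Cluster confidence comes from an ordinary bootstrap
that resamples trait columns with replacement and rebuilds space,
dissimilarity and tree; the reported support of a clade is its recovery
proportion. Multiscale-bootstrap (AU) p-values are deliberately not
implemented — ordinary support answers the same screening question at a
fraction of the machinery, and outputs are labelled accordingly. Genetic
distance between strains is the proportion of co-called biallelic sites
with differing 0/1/2 diploid codes (an allele-sharing variant is optional),
related to phenotypic similarity (correlation of scores at CCR 90%) by
Kendall's tie-corrected $\tau_b$ and an OLS line.

## The synthetic cohort generator

`generate_cohort()` draws a full study: reference baselines per trait
(gaussian baselines normal; positive traits log-normal around realistic
magnitudes, with CV noise traits near 0.15; proportion traits logit-uniform
in 0.2–0.8), founder strains deviating on a configurable subset of traits,
and children derived by breeding events. Effects are injected on the link
scale in units of the family's within-replicate SD, so an effect of size
$\delta$ produces an expected per-replicate Z of about $\delta$ in any
family. Defaults mirror the study design the pipeline expects: 5 replicates
per strain, 11 for the reference; spontaneous isolations shift 5 traits and
mutagen isolations 50, both at $\delta = 1$ within-SD unit (a moderate,
realistic single-step effect); crosses sit at the mid-parent plus an
isotropic inbreeding-deviation term ($\sigma_{dev}=0.5$ by default);
noise inflation multiplies a strain's CV-trait means. Within-replicate
noise: gaussian SD 1, gamma CV 0.2, beta precision 100. Genotypes start
from a shared reference haplotype, give founders Poisson(40) private SNPs,
add Poisson(12) new SNPs per breeding event (mutagen events four times
that), and resolve crosses by averaging parental allele counts with
Bernoulli rounding — so genetic distance tracks lineage depth, as the
genotype–phenotype comparison presumes.

What the generator does **not** emulate: realistic trait–trait correlation
within a replicate (traits are conditionally independent given the strain
effects), image-level artifacts, and cell-cycle-stage trait missingness.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the assumed generative structure, not that any
particular biological dataset will reproduce published values.

## Numerical choices

* GLM convergence: IRLS defaults for gaussian/gamma; beta ML runs BFGS with
  at most 200 iterations and relative tolerance $10^{-8}$; non-converged
  traits are excluded and reported, never imputed.
* A record missing more than 10% of traits is rejected at read time
  (image software emits NA for traits undefined at some cell-cycle stages).
* AIC ties within $10^{-9}$ resolve to the fewer-parameter design.
* UPGMA tie-breaking is made deterministic by lexicographic leaf ordering
  before `hclust`.
* The PP envelope uses the normal quantile times the empirical SD rather
  than empirical quantiles: with ~11 reference replicates an empirical
  2.5% tail is unusable.
* Degenerate inputs raise classed errors (`ml_domain_error`,
  `ml_design_error`, `ml_fit_error`, ...) naming the offending trait, row
  or strain.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on cohorts of the
default geometry (501 traits, 5 replicates, 11 reference replicates):
200 null cohorts for the family-wise error of the Bonferroni screen, 100
cohorts for the mutagen-versus-spontaneous distance ordering, 25 cohorts
for the power of the PP/Dunnett flagging at threefold noise inflation, a
62-segregant panel against a 125-ratio hybrid for the inbreeding-deviation
contrast, and 400 bootstrap resamples for cluster support. These sizes give
Monte-Carlo standard errors comfortably below the margins being tested.

## Known limitations

* The trait catalog ships with generated identifiers and a value-domain
  family heuristic; users holding the true 501-trait definitions and the
  true 220-trait noise list should supply their own catalog.
* Per-replicate Z values for non-reference strains are singleton-level Wald
  statistics; their heavier-than-normal tails are handled by the t
  reference in screens but are not propagated into PCA, matching field
  practice.
* Dunnett's procedure assumes a common variance across strains; grossly
  heteroscedastic PP replicates would call for a robust variant not
  implemented here.
* No hierarchical/random-effect models and no empirical-Bayes shrinkage of
  Z: strains are fixed effects throughout.
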