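---
title: "Models and methods behind wormtrait"
author: "wormtrait authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormtrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrait)
```

# The scientific setting

`wormtrait` analyses experiments in which each of many genetically
identical *C. elegans* individuals is phenotyped for quantitative
reproductive traits — egg-laying onset (ELO, the hour of development at
which the first egg is laid, scored hourly on a 66–74 h window) and early
brood (progeny produced in the first 24 h of egg-laying) — and then
profiled by single-worm mRNA-seq.  Because the population is isogenic and
reared in a common environment, trait variation is non-genetic: it is
driven by controlled differences in *historical* environment (each worm is
born to a day-1 or day-3 adult parent and experiences either constant
20 °C or an early 8 h shift to 25 °C, both binarized as 0/1 covariates)
and by residual "noise" — unknown micro-environmental and intrinsic
stochastic variation.  The package's job is to relate per-gene expression
variation across individuals to per-individual trait variation, to
separate the environmental from the noise component of those associations,
to quantify how predictive aggregate expression profiles are, and to check
that the population really is isogenic.

# The core models

## Per-gene trait association

For worm $i$ in biological replicate $j$ and gene $k$, the scan fits the
random-intercept linear mixed model

$$y_{ij} = \beta_0 + \beta_1 x_{ijk} + u_j + e_{ij}, \qquad
u_j \sim N(0, \sigma^2_u),\; e_{ij} \sim N(0, \sigma^2_e),$$

with $y$ the trait and $x$ the gene's CPM-normalized expression.  The
replicate intercept absorbs batch-level shifts between the five
biological replicates.  Genes are flagged at a Bonferroni-corrected
family-wise level of 0.05 over the scanned gene set: at the genome scale
of 8824 expressed genes this is a nominal threshold of
$0.05/8824 = 5.67\times10^{-6}$.

The engine profiles the likelihood analytically over $\beta$ and
$\sigma^2_e$ given the variance ratio $\lambda = \sigma^2_u/\sigma^2_e$
(the inverse covariance is block-diagonal with a rank-one update per
replicate, so only group-level sufficient statistics enter), and maximizes
the one-dimensional REML profile over $\log\lambda$.  For the
intercept-plus-slope scans, the objective is evaluated for all genes at
once over a $\log\lambda$ grid (step 0.25 on $[-18, 15]$) followed by six
vectorized quadratic-interpolation refinements; a boundary solution at the
smallest grid point is treated as $\lambda = 0$ (no replicate variance),
where the fit reduces to ordinary least squares.  The test suite verifies
the engine against `lme4`, against an independent dense-matrix
grid-search oracle, and verifies the vectorized path against the general
one.  Wald $t$ tests use residual degrees of freedom
$n - p - g$ ($p$ fixed effects, $g$ replicates); a normal-approximation
alternative is available via `dfMethod = "normal"`.  The expression
predictor is CPM by default (`predictor = "logcpm"` switches to
$\log_2(\mathrm{CPM} + 0.5)$).

## Environment effects on expression

Historical-environment effects on expression are scanned with a per-gene
negative-binomial mixed model on the raw counts (log link, fixed effects
parental age and early-life temperature, replicate random intercept,
fitted with `glmmTMB`), using the mean/dispersion parameterization
$\mathrm{Var} = \mu + \mu^2/\theta$.  A log library-size offset is
included by default: library sizes span an order of magnitude in
single-worm libraries, so unadjusted counts would confound depth with
expression (`offset = FALSE` disables it).  Significance is again
Bonferroni-corrected per factor over the scanned set, which is the
stricter "CPM > 1 in every library" gene set — models on raw counts
misbehave for genes with zeros in some libraries, which is exactly why
two filtered sets exist (the laxer "CPM > 10 in at least one library" set
is used for the trait scan, where silent-in-some-worms genes are
informative).

Each fit records an "unexplained variance": the variance of
$\log_{10}((y + 0.5)/(\hat\mu + 0.5))$, a log-scale residual variance
after environment and replicate are accounted for.  Because residual
variance grows with expression, genes are compared through a loess fit
(span 0.75, degree 2, both configurable) of $\log_{10}$ unexplained
variance on $\log_{10}$ mean CPM; the variance $Z$-score is the centred
loess residual divided by the residual SD.  Degenerate inputs are handled
explicitly: genes with zero unexplained variance are excluded (logged in
an attribute), and when all residuals are numerically zero the $Z$-scores
are defined as 0 rather than 0/0.

## Path decomposition

For each trait-associated gene the package fits three models: the total
model above (giving standardized $\beta_1$), the environment-adjusted
model adding parental age and temperature (giving $\beta_2$–$\beta_4$),
and an expression-on-environment model (giving $\beta_5$, $\beta_6$).
Every coefficient is standardized as $b \cdot \mathrm{sd}(x)/\mathrm{sd}(y)$
with sample SDs, so effects are in trait-SD per expression-SD units;
binary environment covariates are standardized by their sample SDs as
well, which makes $\beta_3$–$\beta_6$ comparable across genes (leaving
binaries raw is the other common convention; the package picks one and
states it).  $\beta_1$ is the total effect of expression on the trait;
$\beta_2$ is what survives adjustment for environmental history — the
"noise" component.  Multiplying a standardized beta by the trait SD gives
trait units: with the observed early-brood SD of 20.3, betas of 0.39 and
0.26 correspond to about 7.9 and 5.3 progeny.

Genes are classified by two flags: is $\beta_2$ significant (Bonferroni
over the classified set by default — the classification operates within
the trait-significant genes; `beta2Family` overrides the family size), and
is the gene's expression significantly affected by parental age in the NB
scan?  This yields the four groups noise / parental_age / both / neither.

## Prediction suite

All prediction analyses are deliberately plain multiple regressions
without the replicate random effect — they ask how much trait variance
aggregate expression explains, not how to partition it.

* **Cumulative-PC regression.** PCA is run on the mean-normalized,
  $\log_2$-transformed CPM matrix (pseudocount 0.5; per-gene
  mean-normalization removes abundance scale so components reflect
  relative variation).  PCs are added to a regression in variance order
  and the total $R^2$ recorded; the null band repeats this on the trait
  shuffled `nPerm` times.  Any $k$ independent regressors explain about
  $k/(n-1)$ of an unrelated trait, rising to 1 at $k = n-1$, so the
  observed curve only means something relative to this band.
* **Greedy forward selection.** At each step the gene adding the most
  $R^2$ given the selected set is added, implemented by Gram–Schmidt
  residualization of the candidate pool (exactly the stepwise best-subset
  path; ties within $10^{-12}$ broken lexicographically by gene id so runs
  are reproducible across platforms).
* **Train/test resampling.** 500 (configurable) random half-splits; the
  top-10 genes are selected and refit on the train half, and test
  performance is the squared Pearson correlation of predicted and observed
  traits (`r2Method = "sse"` gives $1 - SSE/SST$ instead; the two differ
  only when the refit line is miscalibrated).  Iteration $i$ is seeded
  `seed + i`, so any single iteration can be reproduced alone.
* **Elastic-net LOOCV.** Mixing parameter $\alpha = 0.5$; for each worm
  the model is trained on the remaining $n-1$ worms with the penalty
  weight chosen by 5-fold inner cross-validation (`lambda.min`;
  predictors standardized within the training fold).  The held-out worm
  contributes nothing to its own prediction — including the inner fold
  assignment, which is seeded independently of the data — and the test
  suite asserts this leakage guard bitwise.  The reported $R^2$ is that
  of the linear fit of observed on predicted values.

One caveat the suite documents rather than hides: in the infinite-penalty
limit each LOOCV prediction equals its own training-fold mean, which is a
*decreasing* function of the held-out trait value, so the $R^2$ of the
predicted–observed fit is degenerate in that limit; the tests therefore
assert the substantive property (predictions collapse to the overall mean
with negligible spread) rather than a meaningless $R^2$.

## Enrichment

Trait effect sizes are compared across chromatin domains (active,
H3K36me3-marked, broadly expressed genes versus regulated,
H3K27me3-marked, developmentally restricted genes) and tissues (soma
versus germline), consumed as a per-gene annotation table.  Three tests:
a two-way ANOVA with interaction on the per-gene effect sizes restricted
to the soma/germline × active/regulated cells, with Tukey HSD on the four
cell means and one-sample $t$-tests of each cell against zero (constant
inputs yield $F = 0$, $p = 1$ by convention); a Kolmogorov–Smirnov
comparison of the proportion of regulated genes in the resampled
predictive sets against 500 random same-size sets from the expressed
background (genes labelled `other` are dropped from the proportion
denominator); and a two-sided Wilcoxon rank-sum test of variance
$Z$-scores, regulated versus active.  Because set proportions take few
distinct values, ties make the asymptotic KS $p$ conservative; the
calibration test asserts the type-I error is at or below the nominal
level.

## Isogenicity check

From a per-site, per-worm base-count table: observations with fewer than
20 reads are dropped; remaining calls are unambiguous (one base),
ambiguous with two bases, or multi (never a candidate).  Sites covered in
at least 10 worms enter the analysis.  Homozygous candidates are the
minority unambiguous observations at a discordant site (at a site with
10 worms reading A and one reading G, the single G worm is the candidate;
modal-base ties break alphabetically).  Heterozygous candidates are
two-base calls with both allele frequencies inside the inclusive 0.3–0.7
window — excluding the skewed patterns typical of sequencing error — at
sites where at least 10 *other* worms are unambiguous for one shared
base.  Rates are candidates per retained site×worm observation, and the
singleton fraction reports how many candidate sites occur in exactly one
worm (variants private to one worm cannot drive associations across 180).
Internally the site-level logic is tabulation over an integer site index,
so tables with $10^7$ observations are processed in seconds to minutes
without joins.

# The synthetic-data generator

Every stage is testable without external data because the generator
emulates the study design: 180 worms in 5 balanced replicates;
independent Bernoulli(0.5) assignment of the two binarized environments
(the realized study design is approximately, not exactly, balanced);
negative-binomial counts with a log-normal gene-abundance profile,
log-normal target library sizes around 5.8 million reads (the study-scale
mean depth), replicate random intercepts (SD 0.1 on the log scale) and
log-scale environment effects (SD log 1.5) on a 5% gene subset for
parental age and a tenth of that for temperature, mirroring the strong
observed asymmetry between the two perturbations (186 versus 2 genes at
the study scale).  Dispersion defaults to $\theta = 2$
($\mathrm{Var} = \mu + \mu^2/\theta$), a moderately overdispersed regime
appropriate for single-individual libraries.  Because NB draws with an
offset cannot hit a pre-drawn library size exactly, the recorded library
sizes *are* the realized column sums (the drawn targets only set the
offset), which keeps CPM self-consistent and makes library-size
conservation hold by construction.

Traits are generated from the same structure the path decomposition fits
— a standardized latent combining per-gene effects on $z$-scored CPM,
standardized environment effects (0.3/0 on brood for age/temperature,
0.3/0.2 on ELO), a replicate intercept, and Gaussian noise sized so the
latent has unit variance — precisely so that $\beta$ recovery is directly
testable.  Early brood is the latent rescaled to SD 20.3 (the study-scale
value) around a mean of 110 progeny and rounded to non-negative integers;
ELO is an affine map (centre 70 h, slope 1.8 h per latent SD) rounded and
clamped onto the integer 66–74 h observation clock, matching how the
trait is actually scored.  Defaults put 3% of genes as causal per trait
with effect SD 0.13, so at the default 1000 genes the aggregate
expression signal explains roughly half of trait variance — the regime
the prediction suite targets.  Causal genes are drawn from the expressed
pool (mean CPM above 10): trait-associated genes in this kind of study
pass the expression filters by construction, and the CPM $z$-scores of
near-silent genes are dominated by single-worm count spikes that no
log-scale predictor can track.  Because the per-trait signal is split
over ~30 independent genes, individual standardized effects are ~0.13 —
a deliberate trade-off: with conditionally independent genes (the
generative structure the package commits to) one cannot simultaneously
reproduce the study-scale aggregate $R^2$ (~0.5) and the study-scale
per-gene effect sizes (median $|\beta_1|$ ≈ 0.38, which at the real scale
reflects many mutually correlated genes sharing the same latent
physiology).  The generator reproduces the aggregate regime; planted
single-gene effects of any size can be supplied explicitly for power
studies.

What the generator does *not* emulate: gene–gene correlation beyond what
shared environment and replicate induce, cell-composition structure,
trans-acting co-regulation, or any coupling between the chromatin
annotation and expression (the synthetic annotation reproduces label
frequencies only).  Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the stated generative model,
not that real tissues satisfy that model.

# Numerical and design choices

* CPM is plain counts-per-million via `edgeR::cpm` (TMM effective library
  sizes available behind `tmm = TRUE`, default off — the downstream models
  consume plain CPM, and whether TMM was applied upstream is a data-entry
  decision, not a model one).
* Filter inequalities are strict (`> 10`, `> 1`), matching how the
  thresholds are stated.
* The log-for-PCA transform divides by the gene mean then takes
  $\log_2$, with pseudocount $\varepsilon = 0.5$ CPM applied before both
  steps; $\varepsilon$ and the predictor scale are exposed because
  reasonable pipelines differ here.
* REML is the default for variance components; no likelihood-ratio tests
  are in scope, so ML refits are unnecessary.
* Each user-facing seed fans out to per-stage seeds through a small
  affine hash (`.stageSeed`), keeping all derived seeds below $2^{31}$
  and letting stages be rerun in isolation.
* Problem sizes in the test-suite Monte-Carlo studies (e.g. 200
  replicates of a 500-gene scan at $n = 180$; planted variant rates of
  $10^{-6}$ over $10^7$ site×worm observations) were chosen as the
  smallest sizes at which the calibration bands are informative at the
  stated Monte-Carlo standard errors.

# Known limitations

* The NB environment scan fits one gene at a time with no information
  sharing across genes (no empirical-Bayes dispersion shrinkage); at tens
  of worms per arm this is well powered, but for small designs a
  shrinkage-based tool would behave better.
* Wald $t$ with $n - p - g$ degrees of freedom is a pragmatic rule; with
  5 replicates it is indistinguishable from Satterthwaite in the scans'
  regime, but it is a convention, and the normal-approximation switch is
  provided.
* Test-set $R^2$ as squared correlation ignores calibration of the refit
  line; the `sse` option is stricter, and the `refit` option reports the
  in-sample $R^2$ of the selected genes' regression refit on the test
  half (the quantity a "total $R^2$ of the same genes in a test set" plot
  shows, inflated by roughly $k/(n_{\mathrm{test}}-1)$ even for unrelated
  genes).
* Because the generator draws genes conditionally independently, the five
  non-causal genes a k = 10 greedy selection adds are the genes with the
  largest *spurious* train-half correlation
  ($\approx\sqrt{2\log G/n}$), and they cost prediction-based test $R^2$
  around 0.1–0.15 at $n = 180$, $G \approx 200$ even when all causal
  genes are found.  Real transcriptomes, with correlated co-expression
  modules, lose less because the extra picks still carry signal.  The
  package's own calibration run documents this attenuation rather than
  masking it; it is the main respect in which synthetic-data prediction
  results understate real-data behaviour.
* The isogenicity rules are intentionally simple read-count filters; they
  do not model base quality, strand, or mapping artefacts, and the
  candidate rates are upper bounds (ambiguity from misalignment inflates
  them).
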