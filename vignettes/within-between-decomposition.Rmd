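---
title: "Separating within- from between-family polygenic score prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating within- from between-family polygenic score prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinwb)
```

## The problem

A genome-wide polygenic score (GPS) is a weighted sum of trait-associated
allele dosages. When a GPS predicts an outcome in a sample of unrelated
people, the association mixes several sources: the direct effect of the
person's own genotype, environmentally mediated effects of *parental*
genotype (parents shape the family environment in ways correlated with the
alleles they transmit — passive gene-environment correlation, or "genetic
nurture"), assortative mating, and population stratification. Dizygotic (DZ)
twin pairs offer a clean separation: co-twins share their family environment
and, on average, half of their segregating additive genetic variation, and
the half they do *not* share is randomized at meiosis. A regression of
within-pair outcome differences on within-pair score differences is
therefore free of every family-level confound, while the between-family
regression absorbs all of them.

`twinwb` implements this decomposition and everything needed to validate
it end to end without access to any real cohort.

## The decomposition model

For twin $i \in \{1,2\}$ in family $j$ the package fits the random-intercept
model

$$Y_{ij} = \alpha_0 + \beta_W\,(\mathrm{GPS}_{ij} - \overline{\mathrm{GPS}}_j)
  + \beta_B\,\overline{\mathrm{GPS}}_j + \gamma_j + \varepsilon_{ij},
  \qquad \gamma_j \sim N(0, \sigma_\gamma^2),\
  \varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2),$$

where $\overline{\mathrm{GPS}}_j$ is the family mean score. Group-mean
centering makes $\beta_W$ (the within-family effect) and $\beta_B$ (the
between-family effect) mutually adjusted. Two derived quantities summarize a
fit: the intraclass correlation
$\mathrm{ICC} = \sigma_\gamma^2/(\sigma_\gamma^2 + \sigma_\varepsilon^2)$,
estimated from the model that includes the fixed effects, and the total
effect $\beta_W (1 - \mathrm{ICC}) + \beta_B\,\mathrm{ICC}$, which is always
bounded by the two coefficients.

### Estimation

Estimation is restricted maximum likelihood (REML). With exactly two members
per cluster the model rotates into orthogonal pair contrasts: differences
$(r_1 - r_2)/\sqrt{2}$ with variance $\sigma_\varepsilon^2$ and sums
$(r_1 + r_2)/\sqrt{2}$ with variance $\sigma_\varepsilon^2 (1 + 2\lambda)$,
$\lambda = \sigma_\gamma^2/\sigma_\varepsilon^2$. The REML criterion is then
profiled over the single ratio $\lambda$ and minimized by bounded 1-D search
on $[0, 10^3]$ (an ICC ceiling of 0.9995, far beyond anything a twin outcome
produces); the boundary $\sigma_\gamma^2 = 0$ is compared explicitly and is
a legal, flagged solution. The package chose REML over ML because it is the
dominant mixed-model convention and unbiased for the variance components; ML
is available via `method = "ml"`.

Two consequences of the rotation are used as exact oracles in the test
suite: when no design column has mass in both the difference and the sum
contrasts (true for the intercept, the two score terms, and any
family-constant covariate such as SES), the GLS fixed effects decouple —
$\beta_W$ equals the through-origin OLS slope of outcome differences on
score differences, and $\beta_B$ equals the OLS slope of pair means on pair
mean scores, independent of $\lambda$. The test suite verifies this equality
to $10^{-6}$ on random cohorts and verifies the full coupled case
(individual-level covariates) against an independent REML implementation
(`lme4`). The same decoupling powers the bootstrap fast path.

Covariates enter as uncentered individual-level fixed effects (only the
score predictor is group-mean centered); a family-constant covariate
therefore loads only on the between part, which is exactly the behaviour the
SES-conditioning contrast needs.

### Inference

The primary inference layer is a cluster bootstrap: families (always both
co-twins together, never individuals) are resampled with replacement to the
original family count, the model is refitted per replicate, and 95%
percentile intervals are taken from the empirical 2.5/97.5 quantiles of the
replicates, using the canonical $(B+1)\alpha$ order-statistic convention of
standard bootstrap software. The
study-scale default is 10,000 replicates; the simulation studies in the test
suite use 400–500, which is enough for interval endpoints stable to about
0.02. Three statistics build on the replicates:

* **difference test** — $z = (\hat\beta_B - \hat\beta_W)/
  \mathrm{SD}_{boot}(\hat\beta_B - \hat\beta_W)$, two-sided normal
  reference. The normal reference is a convention choice; its type-I error
  is verified by simulation (5% ± 2% over 200 null cohorts).
* **attenuation** — $100\,(\beta_B - \beta_W)/\beta_B$, with a percentile CI
  over replicate-wise attenuations. When $|\hat\beta_B|$ is within
  tolerance of zero the ratio is reported as `NA`: a near-zero
  between-family coefficient makes the percentage meaningless.
* **covariate-shift test** — the change of $\beta_B$ after adding a
  covariate (e.g. SES), using *paired* replicates: the raw and adjusted
  models are refitted on the same resampled families, so the replicate-wise
  difference has the correct sampling variance. Unpaired resampling would
  inflate it.

Multiple-testing control across a grid of outcome x score models uses the
Benjamini-Hochberg step-up rule (the corrected threshold is the largest
$p_{(k)} \le (k/m)\,\alpha$), applied once across all fixed-effect p-values
of a run as a single family of hypotheses.

## The synthetic cohort generator

Because real twin cohorts are access-restricted, every estimator is
validated against a forward simulator whose ground truth is known. One
generation of parents is simulated at `n_loci` unlinked biallelic loci
(base effect-allele frequencies uniform on `[freq_low, freq_high]`), mated,
and two offspring per family are produced by Mendelian transmission
(homozygotes transmit deterministically, heterozygotes with probability
1/2, loci independent). Scores are weighted allele sums with weights drawn
$N(0, 1/(2 L \bar p (1-\bar p)))$ and z-standardized, so configured effects
are per-SD. Outcomes follow

$$Y_{ij} = \beta_{direct}\, z_{ij} + \beta_{nurture}\, \bar z_{parents,j}
  + c_{shared}\, C_j + \delta_{subpop(j)} + e_{ij},$$

and family SES is $\lambda_{ses}\, \bar z_{parents,j} + \nu_{ses}\, C_j +
\sigma_{ses}\, u_j$. Design choices worth knowing:

* **Genetic nurture is mediated by the mid-parent score** (the average of
  both parents' standardized scores), so it carries both transmitted and
  non-transmitted parental alleles — the defining property of passive
  gene-environment correlation. With $\beta_{nurture} > 0$ the between
  coefficient exceeds the within coefficient by
  $\beta_{nurture} \cdot \mathrm{cov}(\bar z_{par}, \bar z_{off}) /
  \mathrm{var}(\bar z_{off}) = \tfrac{2}{3}\beta_{nurture}$ under random
  mating, an expectation the tests verify by Monte Carlo.
* **Assortative mating** pairs parents within subpopulation by rank-matching
  a noisy proxy $u = \sqrt{r}\,z + \sqrt{1-r}\,e$ of the standardized
  genetic value; rank matching makes the paired proxies essentially
  perfectly correlated, so the realized mate-score correlation is close to
  $\mathrm{cor}(z,u)^2 = r_{mate}$ — simple, iteration-free, and calibrated
  to ±0.05 in the tests. Any $r_{mate} > 0$ pushes the co-twin score
  correlation above its random-mating value of 0.50.
* **Stratification** draws per-subpopulation allele frequencies from a
  Balding-Nichols beta distribution (mean $p$, variance $p(1-p)F_{st}$) and
  adds a per-subpopulation environmental offset; mating stays within
  subpopulation.
* **Unlinked dosage loci, no haplotypes or recombination** — the design
  under study needs only Mendelian segregation and a weighted allele sum;
  linkage would change nothing the estimators see.
* Oracle columns (`true_*`) are carried in the output table for recovery
  tests; they are not inputs to any estimator.
* One global seed drives all stages through a single random stream, making
  a cohort bit-reproducible from its provenance record.

Defaults (`sim_config()`) describe a moderate, realistic regime: 0.3 per-SD
direct effect, no nurture, shared-environment SD 0.5, residual SD
$\sqrt{0.66}$ (outcome variance near 1), random mating, one subpopulation,
SES loading 0.5 on mid-parent score and 0.5 on shared environment. Where the
underlying design literature does not quantify nurture or mating strength,
the tests state their own values per scenario rather than bending the
defaults.

### What the simulator does *not* emulate

Real polygenic scores carry linkage disequilibrium structure, measurement
error from finite GWAS discovery samples, genotyping batch effects, and
ascertainment; real outcomes have floor/ceiling effects and missingness
correlated with family characteristics. Passing parameter-recovery tests on
this simulator therefore demonstrates that the estimators are correct for
the model they claim to fit — not that any particular real-data estimate is
unbiased.

## Quantile analysis of within-pair differences

`run_quantile()` reproduces the descriptive companion to the decomposition:
signed within-pair score differences (member 1 minus member 2; member order
is fixed, and all oriented quantities are invariant to label swaps) are
split into ten near-equal groups on their absolute value (remainder pairs go
to the lowest deciles; ties break by stable input order), the mean
outcome difference — oriented toward the higher-score twin — is contrasted
between the extreme deciles with a Welch test, and a through-origin
regression of outcome differences on score differences summarizes the
continuous relationship (uncentered $R^2$). Orientation toward the
higher-score twin is the default because it makes the extreme-decile
contrast consistent in sign with the through-origin slope; absolute
differences are available via `oriented = FALSE`. Standardized outcomes can
be mapped back to interpretable units by supplying the original scale SD
(e.g. 15 for an IQ-like metric); means cancel in differences.

Algebraically, the through-origin slope on pair differences equals the
REML $\hat\beta_W$ of the covariate-free decomposition — the package keeps
both routes and the tests assert their equality.

## Relatedness sensitivity model

To check that residual between-family relatedness does not drive results,
`fit_grm_lmm()` swaps the family random intercept for a genome-wide random
effect $g \sim N(0, A\sigma_g^2)$, where $A$ is the genetic relationship
matrix $A_{mn} = \frac{1}{N}\sum_i (x_{im}-2p_i)(x_{in}-2p_i) / 2p_i(1-p_i)$
(allele frequencies estimated from the sample by default, the GREML
convention; monomorphic variants excluded). Estimation rotates into the
eigenbasis of $A$, where the covariance is diagonal, and profiles the
variance ratio exactly as the pair model does. The matrix is dense-eigendecomposed;
at the cohort sizes this package targets (up to ~10,000 individuals) no
sparse approximation is warranted. With sample-estimated frequencies the
off-diagonal mean is slightly negative by construction (about $-1/(n-1)$),
a known property, and DZ siblings average 0.5. When $A = I$ the model
reduces exactly to OLS, which the tests assert to $10^{-6}$.

## Numerical choices and degenerate inputs

* Variance ratio search on $[0, 10^3]$ with explicit boundary comparison at
  $\lambda = 0$; optimizer tolerance $10^{-9}$.
* A perfect fit (weighted RSS below $10^{-12}\sum y^2$) short-circuits the
  search: coefficients are exact, variance components are zero, and the
  bootstrap difference test refuses to run on the resulting degenerate
  (SD < $10^{-12}$) difference distribution.
* Rank-deficient designs drop collinear columns with a warning, but never
  the two score terms — losing those is an error.
* Families without two complete members are excluded with a count
  (listwise pair deletion); `strict = TRUE` turns that into an error.
* Bootstrap replicates that fail (singular resample designs) are dropped
  and counted; more than 1% drops triggers a warning.
* Decile splits: remainder goes to the lowest deciles; all-tied inputs
  split deterministically by stable order.

## Problem sizes used in the validation suite

The shipped tests run the full pipeline at sizes chosen to keep Monte-Carlo
error well inside each tolerance band: 5,000 families x 1,000 loci for the
sibling-correlation checks; 200 independent cohorts of 1,000–2,500 pairs
(150 loci, 400–500 bootstrap replicates) for calibration, power and
coverage; 100 random cohorts for the exact-oracle identities. The number of
loci only sets the granularity of the score distribution, not the behaviour
of any estimator, so the validation cohorts use a few hundred loci rather
than genome-scale counts.

## Known limitations

* Clusters are exactly two members; larger sibships are rejected, not
  silently supported.
* Gaussian outcomes only; no random slopes.
* The GRM model fits `g` as the only random effect (no additional family
  intercept alongside it), matching the sensitivity model it mirrors.
* BH is the only multiple-testing rule; permutation tests and analytic
  cluster-robust standard errors are out of scope — the bootstrap is the
  inference layer.
* The score module intersects weights with available variants and drops
  strand-ambiguous flips; it does not re-weight effect sizes for linkage
  disequilibrium.
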