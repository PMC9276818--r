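---
title: "Methods: twin-design heritability of belief-formation phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-design heritability of belief-formation phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinbelief)
```

This vignette documents the models, assumptions and numerical choices behind
`twinbelief`, in the spirit of a methods section: what is computed, why the
defaults are what they are, and what the package's own validation does and
does not establish.

## The task and its phenotypes

On each of 40 trials a subject estimates the probability of an adverse life
event happening to them (the first estimate, or *prior*, bounded to
[3, 77]%), sees the event's base rate in a demographically similar
population (the *information*, in [10, 70]%), and later re-estimates (the
*second estimate*). For 20 of the 40 events, chosen at random per subject,
the subject also rates familiarity, past experience, vividness of
imagination and negativity on 1–6 scales and attempts to recall the
presented base rate.

Six per-subject phenotypes are derived:

* **update** — mean over trials of the signed belief change
  `|second − first|`, positive when the change is toward the information.
  Overshooting still counts as toward. Trials with `first == information`
  are excluded because "toward" is undefined there; assigning them an
  arbitrary sign would bias the mean, so the exclusion count is logged
  instead (`attr(phen, "n_excluded_equal")`).
* **learning** — the within-subject correlation of signed update with the
  estimation error `|first − information|`. A subject who updates more when
  further off is learning from the information. Requires at least 3 usable
  trials with variance in both series; degenerate subjects get a missing
  score with a warning rather than a meaningless number.
* **memory** — percent of recall probes matching the presented information.
  The default match criterion is exact integer equality, the strictest
  reading; a `tolerance` argument widens it (`|recalled − info| <= tol`)
  since the field has no canonical definition of a "correct" recall.
* **prior** — the mean first estimate over all 40 events.
* **vividness, negativity** (and familiarity/experience as control factors)
  — means of the 1–6 ratings over the rated events only.

Subjects missing more than half of a phenotype's inputs receive a missing
value rather than a noisy estimate. Group-level sanity checks
(`group_mean_tests()`, `prior_rating_associations()`) test the mean update,
the mean learning score and the per-subject prior–rating correlations
against zero with one-sample t-tests.

## Twin similarity by permutation partial correlation

For a phenotype, similarity within pairs is the correlation between the
"twin A" vector and the "twin B" vector, computed separately for MZ and DZ
pairs. Which member of a pair is A is arbitrary, yet it changes the
correlation; `permutation_twin_correlation()` therefore flips each pair's
labels independently with probability ½, 10,000 times, and summarizes the
resulting distribution by its mean and 2.5/97.5 percentiles. Per-pair coin
flips (rather than one global swap) are used because each pair's labelling
is individually arbitrary.

Each correlation is a *partial* correlation: the focal vectors are
residualized (with intercept, by QR projection) on the between-twin
differences `A − B` of the other control factors (prior, familiarity,
experience, vividness, negativity, memory; plus estimation error when the
phenotype is update). This isolates similarity in the focal phenotype from
similarity in related constructs. Two policy rules are enforced centrally in
`control_factors()`: memory is never a control for the prior (the prior
precedes the information, so memory of it cannot have influenced it), and
the focal phenotype is never its own control.

Age needs special handling: twins share one age, so the difference form
would produce an identically zero column that controls for nothing. Age
therefore enters as the pair-level value. Under a label flip the difference
covariates change sign and the focal vectors swap; the age column is
invariant (`build_pair_covariates()` exposes this for testing).

With no covariates the mean of the permutation distribution converges to
the double-entry intraclass correlation, and the test suite checks it
against an independent one-way ANOVA ICC estimator, and against exhaustive
enumeration of all `2^10` assignments on 10 pairs. Pairs missing any needed
value are dropped listwise per phenotype, keeping each phenotype's n
maximal; drops are counted in the result.

## The biometric model

Phenotypic variance is decomposed by maximum likelihood under the classical
twin model. For pair $j$ (members $i = 1, 2$):

$$y_{ij} = \mu + x_{ij}'\beta + A_{ij} + C_j + E_{ij}$$

with additive genetic effects correlated $R_j$ (1 for MZ, ½ for DZ) within
a pair, shared environment common to the pair, and unique environment
independent, giving the pair covariance matrix

$$\Omega_j = \begin{pmatrix} \sigma_A^2+\sigma_C^2+\sigma_E^2 &
R_j\,\sigma_A^2+\sigma_C^2 \\ R_j\,\sigma_A^2+\sigma_C^2 &
\sigma_A^2+\sigma_C^2+\sigma_E^2 \end{pmatrix}.$$

The ADE family replaces $\sigma_C^2$ in the off-diagonal with
$D_j\,\sigma_D^2$, $D_j = 1$ (MZ) or ¼ (DZ) — the standard dominance
coefficient, since DZ twins share both alleles at a locus a quarter of the
time. A dominance-only (DE) model is rejected: dominance is not estimable
without additive effects. Submodels AE, CE and E drop components; all are
compared by $\mathrm{AIC} = -2\mathrm{LL} + 2\,ep$ with ties broken toward
fewer parameters. By convention $ep$ counts the intercept plus the variance
components (E = 2, AE/CE = 3, ACE/ADE = 4) and $df = n_{\text{subjects}} -
ep$; covariate coefficients are not counted. The reported $-2$LL includes
the full Gaussian normalizing constant, so only within-dataset AIC
differences are meaningful, which is all model ranking uses.

Numerical choices:

* **Parameterization.** Variances are squares of unconstrained path
  coefficients, so nonnegativity needs no constrained optimizer and
  boundary solutions (a component pinned at zero) arise naturally and are
  flagged. $\sigma_E^2$ is floored at $10^{-6}$ times the phenotypic
  variance to keep $\Omega_j$ positive definite.
* **Mean profiling.** For fixed variance components the mean parameters
  $(\mu, \beta)$ have a closed-form generalized-least-squares solution, so
  they are profiled out exactly at every likelihood evaluation rather than
  optimized jointly. This reduces a $(3 + p)$-dimensional search to at most
  3 dimensions, is exactly equivalent at the optimum, and is the main
  reason the fitter is robust enough for thousands of replicate fits. The
  sufficient statistics (per-zygosity cross-products) are computed once per
  fit, making each likelihood evaluation O(p²) regardless of cohort size.
* **Multi-start.** Nelder-Mead then a BFGS polish from five starts:
  equal-split variances, Falconer-style moment estimates from the observed
  MZ/DZ covariances, a nested start with the middle component near zero
  (which also guarantees in practice that richer models never fit worse
  than their submodels), and random starts. The optimizer is validated
  against an exhaustive grid search over $(\sigma_A^2, \sigma_C^2,
  \sigma_E^2)$ at 0.01 resolution on a 30-pair cohort.
* **Covariates.** Age, sex (coded female = 1), their interaction and the
  per-subject control factors enter as fixed effects on the mean with
  identical coefficients for both twins. Columns are standardized
  internally for conditioning and coefficients back-transformed for
  reporting; constant columns (e.g. sex in an all-female subset) are
  dropped with a message. Standardized variance components are invariant to
  this coding, which is why exact covariate coding conventions do not
  affect the reported A/C/D/E percentages.

Components are reported as percentages of the residual (post-covariate)
phenotypic variance. 95% confidence intervals are profile-likelihood
intervals on the standardized share: the set of values $h$ whose profiled
deviance (re-maximizing total variance, the split of the remaining
components, and the GLS mean) stays within $\chi^2_1(0.95) = 3.841$ of the
minimum, truncated to [0, 100]. Profile likelihood is the standard for
variance components because it respects the nonnegativity boundary —
lower limits collapse cleanly to 0 there (reported with a boundary flag),
where Wald intervals would go negative. For the single-component E model
the interval is degenerate at 100%.

`stratified_fit()` reruns the whole phenotype-to-fit chain on event
subsets (e.g. events with vs without a known genetic predisposition),
recomputing phenotypes per subset rather than subsetting scores.

## The synthetic cohort generator

The generator exists so that every stage can be validated against known
ground truth. Its defaults are the study conditions: 184 MZ + 80 DZ
same-sex pairs, 40 events (20 rated), estimates bounded [3, 77], base rates
integers in [10, 70], pair-shared ages from a truncated normal(52, 14) on
[18, 90], 88% female pairs. Five standardized subject-level latent traits
(learning rate, vividness propensity, negativity propensity, memory
fidelity, prior offset) are drawn with exact twin covariance algebra:
the additive component is fully shared within MZ pairs and mixed as
$\sqrt{1/2}\,\text{shared} + \sqrt{1/2}\,\text{unique}$ for DZ; dominance
is shared for MZ and correlated ¼ for DZ; C is shared; E is unique. The
default trait decomposition is an AE world with A = 35%, a representative
value for these phenotypes; `var_a`/`var_c`/`var_d`/`var_e` are free, with
ACE and ADE worlds mutually exclusive.

The trial-level equations are deliberately minimal and linear with
clipping — the phenotype definitions, not the generative model, are the
object under test — and every coefficient is exposed in the config so
ground truth is recoverable. Trial noise defaults to 5 percentage points.
Priors load positively on vividness, familiarity and experience signals and
negatively on negativity; the second estimate moves a
`pnorm(learning_rate)` fraction toward the information; recall is exact
with probability `pnorm(memory_fidelity)` and otherwise perturbed by a
nonzero integer; ratings discretize the trial signals onto 1–6 by fixed
standard-normal quantile bins, matching the task's scales.

What the generator does **not** emulate: realistic per-category event base
rates, demographic tailoring of the information, response-time structure,
item effects beyond a shared base rate, dropout/missingness, and any
correlation between the latent traits. Consequently, passing tests
demonstrate that the estimators recover what they are defined to measure
under the stated covariance algebra — not that real task data satisfy that
algebra. Two visible artifacts of the minimal design: recalled values
correlate with priors more strongly than real data would (both are anchored
on the same base rate), and trial-derived phenotype heritabilities are
attenuated relative to the generating trait values by discretization and
trial noise (e.g. the 1–6 vividness means carry less than the full 35%
trait heritability).

## Validation scale and known limitations

The test suite validates: the covariance algebra at 50,000 pairs per
zygosity (tolerance 0.01); the optimizer against the 0.01-resolution grid
oracle on 30 pairs (0.05 deviance units); Monte-Carlo permutation against
exhaustive enumeration on 10 pairs (0.01 on the mean); profile-CI coverage
of a true A = 35% over 200 replicates at the study's 184/80 scale; AIC
model selection over 100 replicates per generating world at 264 pairs; and
agreement between the ML estimate and Falconer's $2(r_{MZ} - r_{DZ})$ at
50,000 pairs per zygosity (2 points). These sizes keep the full suite to a
few minutes on one core while leaving Monte-Carlo error well inside each
tolerance.

Known limitations, inherent to the design rather than the implementation:

* **A/C discrimination power.** With 80 DZ pairs, the deviance separation
  between an AE and a CE explanation of the same MZ/DZ correlations is a
  few units at realistic effect sizes, so AIC ranking between them is
  unstable even when the machinery is exact (the grid oracle agrees to
  0.05 deviance units). At a moderate heritability (A = 40%) the CE model
  wins a nontrivial fraction of replicates at 264 pairs. Interval-based
  summaries (permutation percentile bands, profile CIs) should be read
  alongside the AIC table.
* Each phenotype is decomposed separately; no multivariate Cholesky
  decomposition, sex-limitation or age-moderation models.
* Uncertainty in the permutation analysis is the spread of the
  reassignment distribution, exactly as designed — not a bootstrap over
  pairs, so it quantifies labelling arbitrariness, not sampling error.
* The mixed-effects regression of priors on all ratings simultaneously is
  out of scope; `modelling_table()` exports the long-format table for
  external tools.

## A small end-to-end run

```{r example, eval = FALSE}
study <- simulate_twin_study(twin_sim_config(seed = 1))
phen <- subject_phenotypes(study$trials)
pairs <- pair_phenotypes(phen)
permutation_twin_correlation(pairs, "update", n_perm = 2000, seed = 1)
sel <- model_selection(pairs, "vividness",
                       covariates = default_biometric_covariates("vividness"),
                       seed = 1)
profile_ci(sel$fits[[sel$winner]])
```

The README shows this run's printed output; `run_twin_pipeline()` executes
the same chain for all six phenotypes with per-stage sub-seeds streamed
from one master seed, so stages are independently reproducible and the
whole bundle is byte-identical under a fixed seed.
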