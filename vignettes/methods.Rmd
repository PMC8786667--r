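---
title: "Estimating cause-specific under-5 mortality: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cause-specific under-5 mortality: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5cod)
```

## The estimation problem

Most deaths of children under 5 years occur in countries without complete
vital registration. Cause-of-death information there comes from verbal
autopsy (VA) studies: interview-based surveys that assign probable causes to
child deaths in a study population. These studies are heterogeneous — they
cover different countries and periods, differ in size by orders of
magnitude, and, crucially, report different cause lists: a study that did
not distinguish meningitis from sepsis reports them pooled, and many studies
collapse rare causes into a residual category.

`u5cod` implements a pipeline that turns such data into country-year
cause-specific mortality fractions (CSMFs), deaths, and rates for two age
groups — neonates (0–27 days) and children aged 1–59 months — with 95%
uncertainty ranges, and reports derived quantities (regional aggregates,
annual rates of reduction, target projections).

## The model

For study $s$ with covariate vector $x_s$, the log odds of true cause $c$
relative to a designated base cause $b$ are

$$\eta_{sc} = x_s^\top \beta_c + u_{sc}, \qquad \eta_{sb} = 0,$$

and the true-cause fractions are the softmax
$p_{sc} = e^{\eta_{sc}} / \sum_k e^{\eta_{sk}}$. The observed counts
$y_s$ on the study's *reported* categories follow

$$y_s \sim \text{Multinomial}\!\left(N_s,\; G_s\, p_s\right),$$

where $G_s$ is the study's misclassification (aggregation) matrix: a binary
matrix, determined by the causes the study reported rather than estimated,
with one 1 per column, mapping every true cause to exactly one reported
category. Column sums of 1 make $G_s$ mass-conserving, so studies with
incomplete cause lists still inform the full cause composition.

Priors: non-intercept coefficients get independent Laplace$(0, 1/\lambda)$
densities — the Bayesian LASSO, shrinking covariate effects toward exactly
the kind of sparse solutions covariate selection is after; intercepts get a
wide normal (SD 10, effectively flat over plausible log odds); study random
effects $u_{sc}$ are normal with a shared SD $\sigma$; and $\sigma$ has a
uniform prior on $(0, \sigma_{\max}]$. The bound is the tuning parameter
that controls how much weight individual (especially nationally
representative) studies can pull: the default $\sigma_{\max} = 0.14$
corresponds to cause-odds changes within roughly 30% for most studies
($e^{0.14} \approx 1.15$). Models for low-mortality countries restrict the
random effects to be small ($\sigma_{\max} = 0.01$ by default), since
nationally representative VA is essentially absent there.

### Sampler

The posterior is sampled by adaptive random-walk Metropolis-within-Gibbs
(implemented in C++): one scalar update per free coefficient and random
effect per sweep, plus a log-scale random-walk update of $\sigma$. Step
sizes adapt in batches of 50 during burn-in toward 44% acceptance and are
frozen afterwards, so the kept draws come from a fixed-kernel chain.
Initialisation is $\beta = 0$, $u = 0$, $\sigma = \sigma_{\max}/2$, jittered
per chain; if the posterior is non-finite at the start the chain
re-initialises up to a configured retry limit. Convergence is assessed by
the Gelman–Rubin potential scale reduction factor over $\ge 2$ chains;
parameters with degenerate (zero-variance) chains are reported as 1. All
randomness flows from one integer seed; a fit with the same data, config
and seed is bitwise reproducible.

Gradient-based samplers would mix faster per iteration but are deliberately
out of scope; the scalar-update sampler is transparent, dependency-free
beyond Rcpp, and passes the convergence contract at the problem sizes this
package targets (a 40-study, 80 000-death bundle converges with all PSRF
< 1.1 in well under a minute on one CPU).

### Penalty selection

$\lambda$ is chosen by leave-studies-out cross-validation — studies, not
deaths, are the exchangeable unit. Folds (default 5) are stratified by
study size. Held-out studies are predicted from posterior-mean fixed
effects with their random effect at zero (they are unseen), and the error
is the mean absolute difference between empirical and predicted
reported-category fractions (squared error is available behind
`cv_metric`). Selection uses a one-standard-error rule: the **largest**
$\lambda$ whose mean error is within one SE of the minimum. This is the
concrete reading of "prefer more penalisation when cross-validation is not
decisive"; the multiplier is configurable, with 0 giving the plain
minimiser.

### Strata and model averaging

Separate models are fitted for high- and low-mortality settings, with
different reference causes (chosen for high burden in the respective
stratum): preterm birth complications in the neonatal low-mortality model,
intrapartum-related events in the neonatal high-mortality model, lower
respiratory infections in both child models. Country-years are classified
by all-cause mortality rate per 1000 livebirths: neonates low < 10,
high ≥ 20; children low < 25, high ≥ 35. In the moderate band the two
models' fraction draws are averaged with weight
$w = (r - L)/(H - L)$ on the high-mortality model — the simplest
interpolant that is continuous at both boundaries, so predicted fractions
cannot jump as a country's mortality declines across a threshold.
Averaging operates on fractions (the envelope is applied afterwards), and
cause lists are harmonized first: neonatal diarrhoea, assumed zero in
low-mortality settings, enters the average as an explicit zero. The
uncertainty of the averaging weight itself is not propagated, a known
limitation.

Countries with high-functioning vital registration bypass the model: their
empirical cause fractions are used directly, linearly interpolated between
reporting years and carried forward (or backward) beyond the reporting
span.

### Post-processing

Modelled fractions become deaths through a fixed-order chain, each step
conserving the all-cause envelope to within numerical precision:

1. **Squeezing** — single-cause series estimated by external programmes
   (measles, HIV, tetanus, reported malaria) are taken at face value,
   capped at 90% of the envelope (pro-rata rescale beyond it; the cap is a
   package design choice for pathological inputs), and the remainder is
   distributed over the modelled causes by their fractions.
2. **Splits** — pooled sepsis/meningitis (neonates) and perinatal causes
   (children) are divided using externally supplied proportions; an equal
   perinatal split with a warning is the fallback when no table is given.
3. **Tuberculosis carve-out** — pulmonary TB deaths come out of lower
   respiratory infections, extrapulmonary TB out of the other-communicable
   block, with any extrapulmonary excess reassigned from lower respiratory
   infections; categories are floored at zero and any remaining excess is
   truncated with a warning rather than borrowed from further causes.
4. **Vaccine adjustment** — deaths from causes targeted by Hib, PCV, and
   rotavirus vaccines are scaled by
   $(1 - \text{cov}\cdot VE \cdot PAF)/(1 - \text{cov}_{ref}\cdot VE
   \cdot PAF)$, reflecting coverage attained after the study era; the
   parameters are configuration with documented defaults, not asserted
   external values. Freed deaths are reallocated pro rata.
5. **Crisis attribution** — crisis deaths (events isolated to < 5 years
   with > 10 deaths) are attributed by event type: natural disasters to
   injury, conflict-related malnutrition to the residual group, congenital
   epidemics to congenital abnormalities, or pro rata.

Whether vaccine adjustment precedes or follows squeezing in the original
estimation systems is not documented; the order above is fixed and tested
for conservation, and each step is independently callable for ablation.

### Uncertainty

Uncertainty ranges are 2.5–97.5 centiles (linear interpolation between
order statistics, R's type-7 convention — documented because the ranges are
headline outputs) of Monte-Carlo draws that combine: posterior draws of the
regression parameters; random-effect draws (a country with a nationally
representative study uses that study's posterior $u$ draws; otherwise $u$
is drawn from $N(0, \sigma)$ for uncertainty while the point prediction
uses $u = 0$); lognormal envelope draws; and lognormal draws of each
exogenous single-cause series. Deaths are positive and their uncertainty
ranges asymmetric, hence lognormal rather than normal jitter. Regional
aggregates sum country draws *before* taking percentiles, so within-draw
correlations propagate.

The annual rate of reduction between years $t_1 < t_2$ is the log-linear
rate $100 \ln(r_{t_1}/r_{t_2})/(t_2 - t_1)$ percent per year (the UN-IGME
convention; the source publications do not print their formula). Target
projections assume cause fractions are unchanged when a target all-cause
rate is reached: the required cause rate is the current fraction times the
target rate, compared against the current rate continued at its ARR.

## The synthetic-data generator

Real inputs (multi-country VA databases, UN envelopes, programme-specific
single-cause series) are proprietary, so validation runs on synthetic
bundles whose generating process *is* the model's assumed structure:

* covariates as standardized country-year AR(1) panels (lag-1 correlation
  0.85, emulating smooth development indicators);
* a sparse coefficient matrix (default 2 of 5 covariates truly nonzero,
  effect size 0.8 with alternating sign across causes, intercepts drawn
  from $N(0, 0.5)$);
* study random effects at the bound SD 0.14;
* multinomial death counts on study-specific reported categories, with
  ~30% of studies pooling two causes into their residual category;
* envelopes declining log-linearly from staggered starting rates (120 down
  to 15 per 1000), so the panel spans all strata and several countries
  cross thresholds over time;
* exogenous series as lognormally jittered shares of the envelope.

The default scenario — 40 studies of 2 000 deaths each — was sized so that
a full validation cycle (convergence check, cross-validation, 20 recovery
replicates, conservation suite) completes in a few minutes on one CPU
while leaving the model identifiable; these are desk-scale stand-ins, an
order of magnitude smaller than the real systematic-review database.

Because generator and model share the same structure, passing tests show
*internal* correctness — the sampler targets the stated posterior, the
LASSO recovers sparse truth, every accounting step conserves deaths — not
that the model is well specified for real VA data. In particular the
generator draws genuinely multinomial counts (no overdispersion beyond the
random effects), uses generic standardized predictors with no covariate
measurement error, and contains no VA cause-assignment misclassification
error; none of those simplifications are claims about real data, and the
uncertainty machinery deliberately mirrors the source estimates in
excluding VA misclassification error too.

## Numerical choices and edge cases

* Softmax is computed with max-subtraction; log odds beyond ±745 underflow
  to exact zeros, and a zero reported-category probability facing a
  nonzero count yields a flagged $-\infty$ likelihood.
* Estimate tables are written with 17 significant digits so read-back is
  bit-exact.
* A study reporting causes outside the taxonomy must carry an explicit
  mapping; the default convention routes unreported causes to the study's
  residual category and fails loudly if there is none — guessing a mapping
  silently would corrupt $G$.
* One true cause maps to exactly one reported category ($G$ binary):
  fractional assignment would amount to estimating misclassification,
  which the design explicitly avoids.
* Ties in penalty selection resolve upward (more shrinkage); fold
  assignment is deterministic given study sizes.
* The Gelman–Rubin statistic for a zero-variance parameter is defined as 1.
* ARR is refused (with guidance) for zero rates rather than returning
  $\pm\infty$.

## Worked example

A complete desk-scale run: simulate, fit, check convergence, select the
penalty, predict, post-process, report.

```{r example, eval = FALSE}
tax <- model_taxonomy("child_1to59m", "high")
bundle <- generate_input_bundle(seed = 1)
cfg <- pipeline_config(chains = 4, iterations = 5000, burnin = 2500,
                       seed = 1)

fit <- sample_posterior(bundle$studies, bundle$matrices, tax, cfg,
                        lambda = 2)
max(gelman_rubin(fit))  # < 1.1 on the default bundle

cv <- cv_grid(bundle$studies, bundle$matrices, tax,
              pipeline_config(lambda_grid = c(0.5, 2, 8), chains = 2,
                              iterations = 300, burnin = 300, seed = 2,
                              cv_folds = 3))
select_penalty(cv)

env <- bundle$envelopes[bundle$envelopes$country == "S01" &
                          bundle$envelopes$year == 2019, ]
x <- unlist(bundle$covariates[bundle$covariates$country == "S01" &
                                bundle$covariates$year == 2019,
                              paste0("cov_", 1:5)])
frac <- predict_fractions(fit, x, sample_u = TRUE)
draws <- propagate_draws(frac, env$deaths,
                         envelope_sd_log = env$draw_sd_log,
                         n_draws = 500, seed = 9, preterm_share = 0.6)
summarise_country_year(draws, "S01", 2019, "child_1to59m",
                       env$livebirths)
```

## Known limitations

* The averaging-weight uncertainty and covariate-estimation uncertainty are
  excluded from the ranges (mirroring the source estimates), so ranges are
  somewhat narrow.
* The shared random-effect SD across cause contrasts is the simplest
  structure consistent with a single bound; per-contrast SDs sit behind a
  config flag but are not the tested default.
* The scalar-update sampler scales linearly in studies × causes ×
  covariates; hundreds of studies with many covariates would warrant block
  updates or a gradient sampler.
* Sex-stratified estimation is not implemented.
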