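---
title: "Models and methods behind dmtrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dmtrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dmtrank supports the treatment-switch decision in relapsing-remitting
multiple sclerosis (RRMS): a patient on a disease-modifying therapy (DMT)
that must be discontinued chooses a new one, and the package predicts, for
every candidate DMT, the probability of staying free of relapses and free of
3-month confirmed disability progression (3mCDP) over a horizon of the
user's choosing, then ranks the therapies. This vignette is the package's
own account of the statistical machinery, its assumptions, and the choices
made where the design was genuinely open.

## The two outcome models

Both models are hierarchical Bayesian generalised linear models fitted to a
"switch table": one row per eligible therapy switch, holding the ten
baseline predictors (age, sex, EDSS, the discontinued therapy and its
duration, number of previous DMT substances, whether any previous DMT was
second-line, time since diagnosis, relapses in the preceding 12 months,
time since the last relapse), the newly assigned DMT, the observed exposure
time on it, and the outcomes.

**Relapse model.** The post-switch relapse count is negative binomial,

$$y_i \sim \mathrm{NB}\!\left(\mu_i = \exp(x_i^\top\beta + \alpha_{d(i)} +
\log E_i),\; r\right), \qquad \mathrm{Var}(y_i) = \mu_i + \mu_i^2/r,$$

with exposure $E_i$ in months entering as an offset, so the model learns a
monthly relapse rate. The probability of staying relapse-free over a
horizon $h$ is the negative-binomial zero probability evaluated per
posterior draw,

$$p^{(s)} = \left(\frac{r^{(s)}}{r^{(s)} + \mu^{(s)}(h)}\right)^{r^{(s)}},$$

which is the analytic form of "the fraction of predicted counts equal to
zero" — `nb_zero_prob()` and a posterior-predictive simulation are proven
equivalent in the test suite, so no simulation is needed at prediction time.

**3mCDP model.** The progression indicator is Bernoulli with, by default, a
complementary-log-log link and the same log-exposure offset:
$P(\text{event by } E_i) = 1 - \exp(-E_i e^{x_i^\top\beta' +
\alpha'_{d(i)}})$. This is a discrete constant-hazard formulation: it makes
the exposure adjustment principled for a binary event (twice the follow-up
gives twice the cumulative hazard) and yields a well-defined event-free
probability at any horizon. A plain logit link with log-exposure as a
covariate is available via `model_spec(cdp_link = "logit")`. The synthetic
generator produces 3mCDP events from the same constant-hazard form, so
ground truth and model family coincide and parameter recovery is
well-defined.

**Hierarchy and priors.** Each catalogue DMT gets a partially pooled
intercept $\alpha_d \sim N(0, \sigma)$; therapies absent from the training
data simply keep the pooled prior, which is also how cross-validation folds
handle an unseen therapy. The pooling SD carries a lognormal prior with
median $0.5$ and unit log-SD. A lognormal (rather than the more common
half-normal) is a deliberate numerical choice: a scale prior that is
positive at zero leaves the joint posterior density unbounded along the
hierarchical funnel ($\sigma \to 0$ with all effects pinned at zero), which
destroys mode-centred computation; the lognormal vanishes at zero and keeps
every mode finite. Fixed effects have $N(0, 2.5)$ priors on the
standardised scale, the intercept $N(0, 5)$, and $\log r \sim N(0, 2)$.
Optional DMT-specific slopes for EDSS and recent relapse count
(`dmt_slopes = TRUE`) and user-specified informative priors on individual
DMT intercepts (for newly introduced, sparsely observed therapies) extend
the default intercept-only pooling.

**Eligibility.** A switch enters the table only when at least 6 months have
passed since diagnosis and the latest EDSS on record is at most 6.0 (both
boundaries inclusive); above 6 the scale is too non-linear for a linear
predictor to be trusted.

## Posterior computation

There is no external MCMC engine behind `fit_outcome_model()`; the sampler
is part of the package and was designed around the specific geometry of
these two posteriors:

1. **Mode search in the non-centred parameterisation.** The centred joint
   mode is degenerate (it sits deep in the funnel even with the lognormal
   scale prior), so BFGS with analytic gradients runs on
   $\alpha_d = \sigma\tilde\alpha_d$, $\tilde\alpha_d \sim N(0,1)$, whose
   mode is regular. Each chain starts its mode search from its own random
   initial point.
2. **Sampling in the centred parameterisation** with preconditioned
   Hamiltonian Monte Carlo: the Laplace covariance (transported from the
   non-centred mode through the reparameterisation Jacobian) seeds the mass
   matrix, which is re-estimated from the chain history during warmup; the
   leapfrog step size adapts towards 80% acceptance and trajectory lengths
   are jittered over 1–10 steps to avoid resonances. Centred coordinates
   are used because, once the DMT effects are identified, that posterior is
   close to elliptical — the non-centred one has curved
   $\tilde\alpha$–$\log\sigma$ ridges that defeat any fixed preconditioner.
3. **Interleaved slice-sampling of the pooling scales.** Given the effects,
   the full conditional of $\log\sigma$ involves no data, so an exact
   univariate slice update decouples the scale from the effects at
   negligible cost.

The likelihood kernels (negative-binomial with tabulated count-dependent
special functions, cloglog, logit) are compiled code, and likelihood parts
are cached so the scale updates are free. Convergence is monitored with the
split-chain potential-scale-reduction statistic; production fits use 4
chains × 1000 stored draws after 300 adaptation iterations and are flagged
(not discarded) above a threshold of 1.01. Reduced-draw fits used inside
resampling loops (cross-validation folds, refit ensembles, simulation
replicates) use 2 chains × 400–600 draws with a wider gate of 1.2–1.3,
because the statistic's own sampling noise at that draw budget exceeds the
production threshold; these fits feed point estimates and interval shapes,
not final clinical predictions.

## Ranking, preference shading and reports

`rank_therapies()` computes the event-free probability of every catalogue
DMT for one patient and orders each outcome column by the posterior-mean
probability — the point probability, matching how the clinical display
orders its bars; ranking on the lower interval bound is available as an
option. Ties break first by the narrower 90% interval, then by catalogue
order, so output is deterministic. Therapies excluded by patient or
physician preference are shaded: they keep their computed probability and
interval but carry no rank, and excluding a therapy never changes any other
therapy's numbers. Probabilities are rendered as natural frequencies
("73 of 100 patients like you"), rounded half-up. `explain_prediction()`
decomposes the linear predictor additively into one term per predictor
(posterior-mean coefficient × deviation from the training reference) plus
the patient's percentile position within the training distribution.

## Validation machinery

* **C-index** — the proportion of concordant pairs among all usable pairs.
  For the relapse model a pair is usable when the exposure-normalised
  observed rates differ and concordant when the predicted rates order the
  same way; prediction ties count 0.5. This concrete rule is checked
  exactly against a brute-force enumeration oracle in the tests.
* **MSE / NLL** — mean squared error in outcome units (relapses; event
  indicators) between observed outcomes and posterior-mean predictions over
  each row's own exposure, and the mean negative log posterior-predictive
  mass.
* **Cross-validation** — folds split by patient, never by row, so
  out-of-sample metrics speak to generalisation to new patients.
* **Empirical coefficient intervals** — the same model is refitted many
  times varying only the random-initialisation stream (the data are never
  resampled; it is not a bootstrap), and each coefficient's point estimates
  across refits are summarised by their empirical 5th–95th percentile span.
  A small span means the data, not the initialisation, determine the
  coefficient. Non-convergent refits are excluded; more than 20% exclusions
  aborts the run.
* **Growth monitoring** — for a series of accruing data cuts (the generator
  reproduces the registry's ~1.3% per quarter accrual, with each cut a
  strict superset of the last), the per-cut C-index is tracked as a change
  against the first cut, alongside the interval-span trajectory. A fixed
  held-out cohort can serve as the out-of-sample test set, which removes
  test-set noise from the monitoring curves.

## The clinical-value analysis

`run_scenarios()` reproduces the three adherence scenarios: patients whose
assigned DMT was their own top-ranked therapy, among their top two, or
among their bottom two. Group comparability is restored by propensity-score
weighting on the ten baseline covariates: stabilised average-treatment-
effect weights from a logistic model, Hájek-normalised to mean 1 within
each group, trimmed at the 1st/99th weight percentiles (1:1
nearest-neighbour matching is available behind an option). "Weighting" was
chosen over "matching" as the primary implementation because the outcome
stage is a survey-weighted GLM, which implies weights. The outcome stage
regresses the outcome on the adherence indicator — weighted
negative-binomial with log-exposure offset for relapses, weighted binomial
for 3mCDP — and reports the indicator's slope with a two-sided p-value from
the design-robust sandwich variance. Negative slopes mean lower disease
activity in the adherent group. `compare_with_rct()` implements the
external-comparison harness: filter the cohort by a published arm's
inclusion criteria, predict each patient's event-free probability at the
trial duration under the arm's DMT, and compare the cohort mean and its 90%
interval with the published proportion, flagging differences of 10% or
more; published arm numbers are user-supplied configuration.

## The synthetic registry

`generate_cohort()` produces longitudinal patient records, not model
matrices, so every downstream stage — eligibility screening, predictor
extraction, 3mCDP derivation, CSV round-trips — is exercised on realistic
structure. Defaults emulate the scale and ballpark epidemiology of the
registry setting the models target: 3,119 patients, ~70% female, mean age
~38, baseline annualised relapse rate ~0.4 declining with time since the
last relapse, 3mCDP risk ~12% over two years, exposures log-normal around
24 months (6–60), therapy assignment confounded so that sicker patients
(higher EDSS, more recent relapses) are channelled towards second-line
therapies. Default true DMT effects span a log rate-ratio range of about
0.75 for relapses and 0.55 for progression hazard — large enough for the
ranking to be meaningfully informative, small enough to be realistic.
Relapse dates are placed as a homogeneous Poisson process conditioned on
the drawn count, because only counts and recency feed the models. EDSS
trajectories are reflected random walks on the 0.5 grid, constrained below
the confirmation threshold for event-free patients and carrying an injected
sustained step (with a visit at the progression itself and quarterly
confirmations) for patients with an event — so `derive_3mcdp()` recovers
every generated event exactly. Registry entry (first EDSS recording)
happens shortly before the index switch; earlier switches in the history
therefore fail eligibility, giving exactly one modelling row per patient
with clean ground truth. All randomness flows from one master seed through
per-patient sub-streams, so enlarging a cohort never changes existing
patients — that is what makes growth series true supersets.

What the generator does **not** emulate: site structure (so out-of-sample
splits are by patient, not site), MRI or biomarker measures, informative
censoring or dropout, time-varying covariates within a follow-up period,
secular trends in prescribing, or the marginal distributions of any real
registry beyond orders of magnitude. Passing tests therefore demonstrate
that the machinery is correct and well-calibrated under a faithful data
model, not that real-world performance matches any published figure.

## Decisions taken where the design was open

* **3mCDP step rule.** The standard trial definition is assumed: an
  increase of 1.0 EDSS points versus the pre-switch reference (0.5 above
  reference 5.5), confirmed by a later assessment at least 90 days after
  the provoking increase with no intermediate assessment dropping below the
  threshold. The provoking increase must fall inside the horizon; the
  confirming assessment may fall after it, which makes the event monotone
  in the horizon.
* **"Number of previous DMTs"** counts distinct substances, not episodes.
* **Never-relapsed coding.** Time since last relapse is capped at 120
  months (configurable) rather than infinite, and the cap also applies
  when the last relapse is older than the cap.
* **Intervals are half-open.** An episode covers `[start, end)`; at a
  switch boundary the outgoing therapy is the "current" one. The 12-month
  relapse window is `(index - 12m, index]`.
* **Time unit.** Months of 30.4375 days everywhere; durations are
  real-valued.
* **Horizon range.** The clinical display offers 2–6 years; the functions
  accept any non-negative horizon (a zero horizon returns probability 1
  exactly, a useful degenerate check).
* **Second-line classification** lives in a user-editable catalogue
  (`dmt_catalogue()`), not in code.
* **Random initialisation** for the empirical intervals means random mode
  -search starting points and chain seeds; the data are never resampled.

## Problem sizes used by the test suite

The statistical tests run at sizes chosen to make their Monte-Carlo error
comfortably smaller than the effects they check: parameter recovery on 20
cohorts of 4,000 patients (alternating outcome models); growth monitoring
on nine 1.3%-growth cuts starting from 600 patients — small enough that an
11% total accrual measurably improves the model — with 20 refits per cut
and a fixed 1,500-patient test cohort; weighting calibration on 100
label/outcome replicates over a fixed 8,400-patient cohort (sized so the
confounding-induced bias of the unadjusted estimator is about 3.5 sampling
SDs of the weighted one, making per-replicate bias reduction near-certain
for a working estimator); the scenario
grid on 20 cohorts of 3,000 patients with doubled DMT effect spreads (the
explicitly ranking-informative regime: a prospective power calculation
shows the realistic default progression-effect spread would leave the
rarer 3mCDP cells at roughly 50% power, whereas the criterion being tested
is that a correct ranking is detected in essentially every replicate), and
500 outcome replicates for the type-I error of the scenario tests under a
clean null (equal DMT effects and randomised assignment, 3,000 patients):
size is only defined where the no-effect hypothesis actually holds, and
under channelled assignment the percentile-trimmed weights can retain a
small residual confounding that is a property of trimmed weighting, not of
the test — that behaviour is surfaced separately by the balance diagnostics
and the bias-reduction check.

## Known limitations

The sampler's Laplace-seeded preconditioner assumes a unimodal posterior;
the models here are log-concave given the scales, but exotic designs
(many collinear rare categories) could degrade mixing, which the split-Rhat
flag will surface. The CDP model treats censored-without-follow-up rows by
exclusion rather than modelling the censoring process. The C-index for
counts compares exposure-normalised rates, one of several defensible
conventions. And all calibration statements inherit the synthetic
generator's assumptions listed above.
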