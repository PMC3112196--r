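---
title: "Adjusting mortality predictions for disease-status eligibility criteria"
author: "eligsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting mortality predictions for disease-status eligibility criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cohorts that enroll volunteers show lower disease-specific mortality
than the general population — the *healthy volunteer effect*. One
well-defined component of it is *eligibility-related bias*: when a
study's enrollment criteria exclude people already diagnosed with (or
symptomatic for) the disease of interest, the cohort is depleted of
subjects who were on a short path to death at enrollment. The effect is
strongest in the first years of follow-up and decays as newly arising
disease repopulates the risk pool.

A mortality model fitted to general-population data (or to cohorts
without disease-specific entry criteria) will therefore over-predict
early deaths when validated against such a cohort. `eligsim`
implements a simulation-based adjustment: each subject's ineligibility
window — here, the interval from clinical lung-cancer diagnosis to
lung-cancer death — is modeled explicitly, and simulated deaths whose
implied diagnosis precedes enrollment are rejected and re-simulated,
because such a subject could never have volunteered.

The package targets the setting of a heavy-smoker chemoprevention
cohort (6,877 placebo-arm subjects, ages 50–69, at least 20 pack-years,
current smokers or quit within 6 years) with individual smoking
histories, but every component is generic.

## The diagnosis-to-death interval

The ineligibility window `W` is approximated by an exponential
distribution. Its mean is estimated from patient-level survival
records:

1. Kaplan–Meier curves are estimated separately by AJCC stage I–IV
   (`km_estimate()`, via the product-limit estimator in the `survival`
   package).
2. The stage curves are combined as a *mixture on survival
   probabilities*, `S(t) = sum_s w_s S_s(t)`, using an external
   registry stage distribution at diagnosis
   (`weighted_overall_curve()`, default weights I 16.22%, II 2.91%,
   III 32.64%, IV 48.23%). Re-weighting removes referral bias in the
   stage mix of a tertiary-center case series.
3. The overall median `x_med` is the first time the weighted curve
   reaches 0.5 (`km_median()`; no interpolation — the standard
   convention, and the step structure of the mixture is preserved by
   evaluating it on the union of the stage event-time grids).
4. The exponential mean is `x_med / ln 2` (`exponential_from_median()`;
   months are converted to years). A 17-month median gives a 2.04-year
   mean; an 11-month median gives 1.32 years.

Stage curves are carried forward beyond their last event time; this is
conservative for the median search and matters only if the weighted
curve would otherwise cross 0.5 in an unobserved tail.

## The mortality model

Lung-cancer death is driven by a tail function `S(t; d)`: the
probability of not dying of lung cancer by age `t` given smoking
history `d` (start age, quit age, cigarettes/day) and gender. The
bundled implementation is a two-stage clonal expansion (TSCE) model:
normal cells acquire an initiating event at rate `nu` (per year, cell
number absorbed); initiated cells divide at `alpha`, die or
differentiate at `beta`, and transform malignantly at `mu`; malignancy
leads to death after a fixed lag. Smoking multiplies `nu` and `alpha`
by `1 + coef * dose^exponent` while active.

The no-malignancy probability is computed exactly: with piecewise
constant parameters on the segments before initiation, during smoking,
and after cessation, the clone-extinction probability satisfies a
Riccati equation whose closed-form solution is propagated backward
across segments, accumulating the integrated initiation hazard
(`tsce_survival()`). The implementation evaluates the Riccati ratio in
log-magnitude (softplus) form so that long segments cannot overflow,
and guards the two fixed points of the flow; degenerate segments
(`alpha ~ 0`, repeated roots) fall back to adaptive ODE integration.
The test suite verifies the propagation against an independent
segment-restarted Runge–Kutta integration to 1e-8 relative error on
randomized parameter draws.

The default parameter set is a synthetic placeholder — *not* a fit to
any cohort — tuned once to realistic magnitudes (lifetime lung-cancer
mortality below about 1.5% for never-smokers and several tens of
percent for lifelong heavy smokers, with a follow-up death fraction of
a few percent for a heavy-smoker cohort aged around 58). All adjustment
properties tested by the package are parameter-independent; substantive
predictions require externally fitted parameters supplied through
`tsce_params()`.

## The rejection-sampling routine

For a subject with enrollment age `t0`, end of follow-up `t1`, and
history `d` (`simulate_subject()`):

1. Draw `u ~ Uniform(0, S(t0; d))` — the subject's death age is
   conditioned on surviving to enrollment.
2. If `u <= S(t1; d)`: no lung-cancer death in follow-up; retire.
3. Otherwise the death age is `t* = S^{-1}(u)`, found by bisection on
   the monotone tail function to `|S(t*) - u| <= 1e-9`. Draw
   `w ~ Exponential(mean)`; the diagnosis age is `t* - w`.
4. If the diagnosis age is at or after `t0`, accept; otherwise the
   subject would have been ineligible — reject and restart the whole
   draw (fresh `u` *and* fresh `w`).

Restarting both draws makes the accepted outcome follow exactly the
per-attempt law conditioned on acceptance, which is what the analytic
oracle computes (below). The measure-zero tie `diagnosis age == t0` is
accepted, and a death exactly at `t1` counts as in follow-up. A
rejection cap (default 10,000) turns the pathological case "death
before enrollment almost surely" into a clear error instead of an
endless loop.

Deaths are binned into follow-up years `(t0 + k - 1, t0 + k]`
(boundaries to the earlier year). A trial simulates every cohort
subject once; `run_trials()` repeats the trial (default 5,000
replicates) and summarizes annual, cumulative, and total deaths as
replicate means with empirical 2.5%/97.5% percentile bands, overall and
by gender. `compare_observed()` lays observed deaths — binned with the
same rule — beside the predictions.

### Random streams

Each (replicate, subject) pair gets its own substream, seeded by a
multiplicative congruential mix of `(seed, replicate, subject index)`
carried out exactly in doubles below 2^53. Results are therefore
reproducible from the seed and the cohort order alone, independent of
any interleaving, and reordering the cohort only permutes the
stream-to-subject assignment. Distinct substreams are not provably
non-overlapping, but at the package's simulation sizes (well under 10^7
draws per run) overlaps are statistically irrelevant.

## The analytic oracle

`oracle_decompose()` computes the exact stationary law of the accepted
outcome for one subject: with `f = -dS/dt` and
`F_W(w) = 1 - exp(-w / mean)`, the per-attempt acceptance mass is

    Z = S(t1)/S(t0) + (1/S(t0)) * int_{t0}^{t1} f(t) F_W(t - t0) dt,

the accepted no-death probability is `S(t1)/(S(t0) Z)`, and the
accepted probability of a counted death in year bin `(a, b]` is
`(1/(S(t0) Z)) int_a^b f(t) F_W(t - t0) dt`. The decomposition
normalizes to 1 by construction; the quadrature is adaptive
(`stats::integrate`). The density uses the model's analytic form when
it exposes one (the toy exponential model does); otherwise a central
difference of `S` with step 1e-5 years. Differencing amplifies the tail
function's own numerical jitter, so the finite-difference path walks a
graded tolerance ladder (1e-7 down to 1e-4 relative) and keeps the
tightest quadrature that converges — ample precision for checking a
Monte-Carlo simulator whose own resolution is ~1e-3.

The oracle deliberately shares no sampling code with the simulator: the
test suite drives 200,000 accepted draws per configuration through the
batch simulator and compares every per-year probability to the oracle
at the 3-binomial-SE level across randomized configurations.

## Synthetic data

No individual-level data from the motivating trial or case series are
public, so the package generates its own.

`generate_cohort()` emulates the published *marginal* composition of
the heavy-smoker placebo arm: per gender, enrollment age
truncated-normal on [50, 69], pack-years truncated-normal above 20,
follow-up truncated-normal capped at 19.5 years. The location of each
truncated normal is calibrated by root finding so the *truncated* mean
equals the published mean (a plain truncation would shift the age mean
by about +0.4 years). Smoking intensity is drawn from a
{10, 20, 30, 40} cigarettes/day mixture restricted to levels that keep
the implied initiation age above 12, and the initiation age is solved
from the drawn pack-years so that exposure accumulated by the end of
smoking matches; 60% of subjects are current smokers, the rest quit
uniformly within 6 years before enrollment. The pack-year location is
additionally pre-compensated (again by root finding, using the exact
mean of a capped truncated normal) for the rare subjects whose
initiation age must be floored at 12 with pack-years rescaled.

What this generator does *not* emulate: the joint distribution of age,
intensity, and duration (unpublished — only marginals are matched),
non-smoking exclusion criteria, attrition patterns in follow-up, or any
correlation between smoking history and follow-up length. Passing tests
therefore demonstrate correctness of the machinery on a cohort with the
published marginal composition, not predictive accuracy for the real
trial.

`generate_survival()` draws stage-stratified exponential survival times
with given per-stage medians, stage mix, and an independent
`Uniform(0, c_max)` censoring time whose upper bound is calibrated so
the expected censored fraction matches the request — independence keeps
the Kaplan–Meier estimate consistent (censoring a record at a uniform
fraction of its own death time, a tempting shortcut, is informative and
biases the median upward by over a month at these scales).
`calibrate_stage_medians()` scales a realistic stage profile (I:II:
III:IV = 60:35:14:6 months) so the weighted mixture median is exactly a
target value, enabling end-to-end parameter-recovery tests: with a
17-month mixture median, the full pipeline at n = 50,000 recovers a
mean near 2.04 years, with a sampling SE of about 0.12 months on the
median (about 0.015 years on the mean).

## Numerical and design choices

- **Bisection, not Newton**, inverts the tail function: `S` is monotone
  and cheap; robustness beats speed at cohort scale.
- **Tolerances**: tail inversion 1e-9 on the probability scale; TSCE
  closed form vs. ODE 1e-8 relative; oracle normalization 1e-8;
  quadrature 1e-10 relative with an analytic density.
- **Degenerate inputs**: all-censored survival data, curves that never
  reach 0.5, stages with positive weight but no events, zero-hazard
  follow-up windows, and subjects whose diagnosis almost surely
  precedes enrollment all raise targeted errors rather than returning
  quietly wrong numbers.
- **"Still smoking"** is an empty quit age, treated as smoking through
  the end of the evaluated horizon.
- **Interval sources** are exclusive by construction in `run_config()`:
  a fixed mean, estimation from files, or no adjustment.
- **Problem sizes**: the bundled tests run replicate counts of 30–250
  on toy cohorts of 50–800 subjects and 200,000-draw oracle
  comparisons; `scripts/acceptance.R` simulates the full 6,877-subject
  synthetic cohort at 150 replicates. These sizes were chosen to give
  Monte-Carlo standard errors comfortably inside the tested tolerances;
  the 5,000-replicate default of `run_trials()` matches the protocol
  scale intended for real use.

## Limitations

- The adjustment removes *eligibility-related* bias only. Self-selection
  of health-conscious volunteers is a distinct, harder-to-quantify
  component of the healthy volunteer effect and is out of scope.
- The interval is exponential and shared across gender and age; the
  interval could be extended to include pre-diagnosis symptomatic time,
  but no such model is provided.
- The interval and the age at death are treated as independent in the
  rejection routine; the oracle computes the stationary law of exactly
  this routine, so simulator and oracle are consistent by construction,
  and any residual dependence bias is a modeling, not implementation,
  question.
- The default TSCE parameters are placeholders; absolute predicted
  death counts under them are illustrative only.
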