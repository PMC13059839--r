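---
title: "Methods: cluster-randomised infant mortality analysis with dual death enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-randomised infant mortality analysis with dual death enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtmort)
```

## The setting

Community-wide (mass) administration of azithromycin to young children has
been tested in several cluster-randomised trials as an intervention against
child mortality in the Sahel. `crtmort` implements the statistical pipeline
of such a trial with infants (children aged 30–364 days) as the target
population: primary-care catchment areas are the unit of randomisation
(allocated 2:1 to drug versus placebo), treatment is distributed every six
months, and the endpoint is the all-cause death rate per 1000 person-years
at risk at the cluster level.

Mortality in such settings is hard to enumerate. The pipeline therefore
models **two observation streams over one underlying truth**:

* a **biannual census**: every child's vital status (alive, dead, moved,
  unknown) is recorded at each round, so deaths are localised only to an
  inter-census interval;
* a retrospective **birth history** at the study endpoint: all women aged
  15–52 are asked about live births in the previous three years, which
  captures exact dates but misses a fraction of deaths (under-ascertainment
  with some sensitivity below 1).

Every stage downstream — accrual, inference, bias analysis, life table,
power — consumes or corrects these streams.

## The synthetic trial generator

`sim_config()` fixes the data-generating truth; `simulate_trial()` draws one
trial from it. Defaults are the trial's design conditions:

| parameter | default | meaning |
|---|---|---|
| `n_clusters`, `allocation_ratio` | 516, 2:1 | clusters randomised, 344 treated : 172 control |
| `baseline_rate` | 0.01 /PY | control-arm death rate among 30–364 day olds (10 per 1000 PY) |
| `effect_irr` | 1 | true multiplicative effect (null, as the trial estimated) |
| `cv` | 0.33 | between-cluster coefficient of variation of true rates |
| `n_rounds`, `round_interval_days` | 4, 182 | biannual MDA rounds |
| `births_per_cluster_per_round` | 90 | live births per cluster per interval |
| `sensitivity_bh` | 0.85 | probability a true death is reported in the birth history |
| `move_prob` | 0.05 | per-interval out-migration probability |
| `background_rate` | 0.03 /PY | hazard outside the eligible ages (neonatal mortality is several-fold higher than postneonatal, hence > `baseline_rate`) |
| `unknown_prob` | 0.02 | chance an alive child is censused as "unknown" (missed household) |

Where the design states a value (rates, cv, allocation, round spacing) the
default is that value; the remaining defaults (births per cluster, movement,
background hazard, unknown rate, sensitivity) are set once at magnitudes
typical of Sahelian field trials and DHS validation work, and are not tuned.

Modelling choices:

* **Between-cluster heterogeneity is gamma.** Only the coefficient of
  variation is specified by the design, not the law; a gamma with
  `shape = 1/cv^2` moment-matched to the arm mean is the standard
  overdispersion model for rates (it makes cluster death counts negative
  binomial) and is strictly positive. `cv = 0` degenerates to the arm mean.
* **Exact day counts.** The calendar is an integer day index from the first
  MDA round; ages are exact day differences; no real-date parsing. All
  intervals are half-open `[start, end)` and person-years are days/365.25.
* **Death clock.** Each child's age at death is drawn from a
  piecewise-constant hazard: `background_rate` before day 30 and from day
  365, the cluster's rate in between. Deaths after the final census are
  unobservable by either stream and are not recorded as trial truth.
* **Movers never return**, and a death after out-migration is not part of
  the trial's truth (the child has left the study area).
* **Independent RNG sub-streams** (rates, births, deaths, migration, census
  noise, degradation) are derived from the one seed, so components can be
  varied independently; a fixed seed reproduces the dataset byte for byte.

`degrade_to_birth_history()` retains live births in the 3-year recall
window and reports each true death with probability `sensitivity_bh`;
missed deaths appear as alive children (the interviewed mother omits the
death, so the child also accrues spurious person-time). Movers are
retained and censored at the move day — the enumeration rule for movers in
birth histories is not pinned down by the census rule, and censoring at the
terminal event is the natural analogue (a sensitivity analysis could drop
them instead).

What the generator does **not** emulate: seasonality of births or deaths,
within-cluster household structure, recall errors in dates (only
missingness of whole deaths), return migration, differential
(arm-dependent) misclassification, and insecurity-driven cluster loss
beyond what a user imposes by dropping clusters. Passing tests on this
truth therefore validate the estimators' statistical behaviour, not the
field realism of any particular data set.

## Person-time accrual

`eligible_interval()` defines the risk window `[dob + 30, dob + 365)`: the
days on which the child's age in completed days lies in 30–364.

**Birth history** (`accrue_birth_history()`): for each cluster round, a
child contributes the length of `risk ∩ [mda, mda + 182) ∩ [dob,
terminal)`, where terminal is the earlier of death and move; the death is
counted when the death day falls in `risk ∩ window` and precedes any move.
The six-month outcome window is exactly 182 days (the design says "every 6
months" without defining days), which also makes consecutive windows
contiguous and non-overlapping; schedules with rounds closer than the
window are rejected.

**Census** (`accrue_census()`): per inter-census interval, alive→alive
children contribute `risk ∩ interval`; alive→dead children contribute half
of that intersection — half of the *eligible* time, not half the raw
interval, so the denominator stays on the eligible-time scale — plus one
death; moved or unknown children contribute nothing. Deaths whose age at
death lies outside 30–364 days are not counted (they are out of the
endpoint's age range even though the interval contributes person-time up to
its half-time); when a death day is genuinely unavailable the death is
attributed whenever the child had any eligible time in the interval.

Two documented consequences: a death on the first eligible day of a window
counts with zero accrued person-time (rate models exclude zero-person-time
clusters explicitly); and the census estimator is a few percent
anti-conservative on the rate scale, because "unknown" rounds delete
survivor person-time but never deaths, and the half-interval convention is
exact only for deaths uniform in the interval. Both are properties of the
enumeration rules themselves, visible when the accrual is run against the
generator's known truth.

Subgroups (`subgroup_split()`): sex, region and CSPS type partition
children whole; the age-band split (1–5 vs 6–11 completed months) cuts each
child's risk window at day 183 from birth (completed-month convention), so
band aggregates sum *exactly* to the unsplit aggregates — an invariant the
tests assert, alongside equality with a brute-force day-by-day counter on
small instances.

## Between-arm inference

`fit_irr()` is the primary model: cluster-level Poisson regression of
deaths with a log person-time offset and arm as the only covariate. With a
single binary covariate the point estimate is algebraically the ratio of
pooled rates (asserted to 1e-10 in tests); the variance is the sandwich
estimator clustered on the randomisation unit. No small-sample degrees-of-
freedom correction is applied by default — with hundreds of clusters the
G/(G−1) factor is immaterial — but `small_sample = TRUE` enables it. The
model family is quasipoisson purely so the bias analysis can pass
fractional corrected death counts; point estimates are identical and the
model-based dispersion is discarded in favour of the sandwich. An arm with
zero deaths yields IRR 0 (or Inf) with an undefined CI rather than an
error.

`bootstrap_ird()` resamples clusters with replacement, stratified by arm to
preserve the 2:1 design (unstratified available behind a flag), recomputes
the rate difference per 1000 person-years each time, and reports the
2.5/97.5 percentile interval. Replicates where an arm loses all its
person-time are redrawn and counted.

`permutation_p()` re-randomises arm labels preserving the per-arm cluster
counts and uses |log pooled-rate-ratio| as the two-sided statistic (the
design names the test but not the statistic; the absolute log ratio is the
natural exchangeable choice and is invariant to which arm is called
treated). The p-value carries the standard +1 Monte Carlo correction.
Replicates with zero deaths in an arm are infinitely extreme and count
against the observed statistic; all-zero data give p = 1 by convention.

## Probabilistic bias analysis

Birth-history under-ascertainment is nondifferential by design (interviewers
and mothers are masked to allocation), so each iteration draws a single
sensitivity `s` from a beta prior shared by all clusters, divides every
cluster's deaths by `s` (fractional counts; an inverse-binomial stochastic
variant is available), and recomputes the IRD. Random error representing
the estimate's sampling uncertainty is then added as `e/s` with
`e ~ Normal(0, sd_IRD)`, where `sd_IRD` is the cluster-bootstrap standard
deviation of the *uncorrected* IRD — dividing the error by the same `s`
puts it on the corrected scale, since rescaling the deaths rescales the
estimate's sampling error with it. The calibration simulation in the test
suite shows why this matters: adding raw-scale error after the correction
covers the fully-ascertained IRD only ~85% of the time at s = 0.8, while
the corrected-scale error restores ~95% coverage. The reported corrected
IRD is the median of the draws; the 95% uncertainty interval their
2.5/97.5 percentiles. Specificity is assumed perfect (no false deaths are
corrected away), matching how such interviews actually err.

The beta prior is specified by a mean and 95% interval. `beta_from_moments()`
fits both shape parameters to the two percentiles by least squares (with a
weak penalty towards the stated mean), initialised by moment matching with
`sd = (high − low)/3.92`. A skewed beta cannot in general match an
arbitrary mean *and* both percentiles exactly; the percentiles win because
they are what the stated interval asserts (achieved within 0.005; the mean
within about 0.02). A degenerate interval is treated as a point mass. The
package default prior — mean 0.85, 95% CI (0.70, 0.95) — reflects published
full-birth-history validation estimates for under-five death ascertainment;
it is a user input, not a constant of nature.

## Synthetic-cohort life table

`segment_probabilities()` implements the DHS synthetic-cohort device over
age segments 0, 1–2, 3–5 and 6–11 completed months (day bounds [0,30),
[30,91), [91,183), [183,365) — the completed-month readings of the labels).
For a calendar reference window, each segment's death probability is deaths
at in-segment ages within the window divided by a weighted count of
children exposed to the segment: full weight for cohorts whose passage
through the segment lies inside the window, half weight for partially
exposed cohorts (the DHS convention), zero for children dying before
reaching the segment. `cumulative_mortality()` combines segments as
`1000 × (1 − Π(1 − q_j))` — deaths per 1000 live births. Confidence
intervals come from a cluster bootstrap of the entire life-table
computation (the method itself does not prescribe one). Under a constant
hazard the estimator reproduces the closed form `1 − exp(−365h)` within 2%,
and refining the segment grid leaves the cumulative probability essentially
unchanged (the product telescopes) — both asserted in tests.

## Power and detectable effect

`power_for_effect()` uses the normal-approximation comparison of two
incidence rates with between-cluster variation, in the Hayes–Moulton form
generalised to unequal arms: the rate difference is tested against
`sqrt(Σ_j (λ_j/y + k²λ_j²)/c_j)`. The textbook `c − 1` small-sample variant
is available but off by default (hundreds of clusters). At the planned
design — λ0 = 0.01/PY, 16% reduction, k = 0.33, 344:172 clusters, 327 PY
per cluster, α = 0.05 — the formula gives 78.6% power, consistent with the
planned 80% given that the exact formula variant behind a design claim is
rarely recoverable; a 600-trial simulation at the same design agrees within
the Monte Carlo error. `detectable_effect()` inverts the power function
numerically (17.1% at 80% power after 10% cluster loss), and
`design_effect()` reports the variance inflation `1 + k²λy ≈ 1.36` as a
diagnostic rather than an input.

## Cause-specific analysis

`filter_causes()` applies the inclusion rules for externally coded verbal
autopsies: assignments at likelihood ≤ 20% are dropped (strictly), the
highest-likelihood surviving cause is each child's primary cause, and a
cause is compared only when it has more than 5 children overall and at
least one per arm. `cause_irrs()` refits the primary cluster Poisson model
per cause with the cause's deaths as outcome and *total* person-time as
offset (competing causes do not shrink the denominator — the rates are
cause-specific mortality rates, not cause-conditional ones), then applies
Bonferroni over the retained causes. The cause-coding algorithm itself is
out of scope; `simulate_cause_assignments()` only furnishes synthetic
coder-style output so the stage can be exercised end to end.

## Numerical and testing choices

* Simulation scales in the test suite are chosen to finish in minutes while
  staying in the regime each method assumes: type-I error of the
  permutation test over 1000 null trials of 30 clusters; bootstrap coverage
  and bias-analysis calibration over 500/200 trials of 90 clusters (the
  percentile bootstrap needs a few dozen clusters per arm before its
  asymptotics bite — the real design has several hundred); effect recovery
  over 200 trials of 300 clusters; power simulation over 600 trials at the
  full 516-cluster design.
* All resampling is seeded, restores the caller's RNG state, and is
  invariant to the order of the input rows (aggregation is keyed by
  cluster).
* Degenerate inputs have defined behaviour rather than errors where the
  field produces them naturally: zero-death arms (degenerate IRR contract),
  zero-person-time clusters (excluded and counted), zero-exposure life-table
  segments (flagged NA), all-zero permutation statistics (p = 1).

## Limitations

The pipeline treats cluster aggregates as the unit of analysis throughout,
as the design prescribes; it offers no individual-level frailty or
random-effects alternative. The bias analysis corrects sensitivity only.
The census estimator's small anti-conservatism under unknown-status noise
is inherent to the enumeration rule, not removed. And because the generator
is the only source of truth for the property tests, conclusions about field
data inherit the generator's simplifications listed above.
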