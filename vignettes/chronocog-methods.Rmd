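---
title: "Methods: chronotype, free-living activity and time-of-day cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronotype, free-living activity and time-of-day cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocog)
```

# The scientific problem

Chronotype — an individual's intrinsic circadian timing preference — shapes
both when people are physically active and how their cognitive performance
varies across the day. A *synchrony effect* is the hypothesis that performance
is best when testing time aligns with the chronotype-preferred time of day:
late chronotypes should look worst in the morning and catch up towards the
evening. Free-living studies probe this with three data streams per
participant:

1. a **morningness questionnaire** (the 13-item Composite Morningness
   Questionnaire, CMQ; totals 13–55, higher = earlier chronotype);
2. a week of **wrist actigraphy** (triaxial vector magnitude per 60-s epoch);
3. repeated **mobile cognitive testing** (the XNA battery: XNA1, 17 trials of
   stimulus-oriented attending; XNA2, 27 trials adding stimulus-independent
   attending and working-memory updating), scheduled near 09:00 and 21:00 on
   alternating days.

`chronocog` implements that full analysis chain as tested, reusable functions,
plus a synthetic cohort generator with the same statistical structure, so the
inference layer can be validated by simulation (parameter recovery, type-I
error) without access to any raw cohort.

# Chronotype scoring and grouping

`score_cmq()` sums the point values of the 13 selected options. The published
instrument is copyrighted, so the package ships a *structural* key — ten
4-option and three 5-option items, each option worth its index — which is the
only 4/5-option mix consistent with the printed 13–55 range. Users holding the
instrument can drop in the verbatim key (`read_cmq_key()`); every downstream
result depends only on the total.

`assign_quintiles()` cuts the ranked scores at the empirical 20/40/60/80
percentiles. Two conventions are deliberate and documented because the
literature does not fix them:

* **Direction.** The CMQ runs opposite to some chronotype scales: a *higher*
  score means an *earlier* chronotype, so the top quintile is labelled
  `early`.
* **Ties.** Tied scores never straddle a boundary; a tied block is placed in
  the lowest group index any member would occupy. Group sizes may therefore be
  unequal (real cohorts show e.g. 15/15/13/16/16 at n = 75), and a fully tied
  cohort collapses into one group with a warning.

# Actigraphy features

All activity features share one window convention: **trailing, half-open
windows `(t − 60 min, t]` indexed by their end time**. This makes the rolling
activity series and the "activity in the previous hour" model covariate
definitionally identical — the covariate at a session timestamp is the rolling
value at the truncated window end (`activity_prior_window()` vs
`rolling_auc()`, cross-checked in the tests).

* **AUC.** The 60-min area under the curve is the plain sum of the 60 epoch
  values (a left Riemann sum at fixed epoch width). Units are arbitrary
  activity units; only contrasts matter.
* **Wear time.** Devices record zeros when off-wrist. Non-wear is defined as
  missing epochs plus any maximal run of ≥ 60 consecutive zero epochs — a
  simple, replaceable heuristic (the run length is an argument). Exclusion is
  *strictly* below 90% wear, so a participant at exactly 0.90 is retained.
* **Daily peaks.** Days run local midnight to midnight; each day's peak is the
  window-end time of day with maximal AUC, earliest occurrence winning ties
  (deterministic); days with under half their windows observed are skipped.
  Note the trailing convention places a pure cosinor's daily peak half a
  window (30 min) after its acrophase.
* **Peak averaging is circular.** Clock times live on a circle; averaging
  23:30 and 00:30 arithmetically gives 12:00, the circular mean correctly
  gives 00:00. Peaks are mapped to angles `2πh/24`, unit vectors averaged, and
  mapped back. When the resultant vector length vanishes (fully dispersed
  peaks) the mean is undefined and the function says so rather than returning
  an arbitrary number. The arithmetic mean is available via
  `mean_peak_time(method = "arithmetic")` for sensitivity analysis.

Timestamps are local and timezone-naive throughout (single-site design); DST
is ignored.

# Cognitive session cleaning

* **Validity filter:** trials with reaction times shorter than 125 ms or
  longer than 5000 ms are removed; the bounds themselves survive.
* **Errors are response-based, not latency-based:** the error count is taken
  *before* RT filtering, so removing slow/fast trials never changes it.
* **Engagement screen:** sessions with ≥ 8 errors on XNA1 or ≥ 10 on XNA2 are
  flagged as low engagement. The thresholds are read as "at or above excludes"
  (the natural reading of a minimum triggering count); they are arguments, as
  is whether flagged sessions are dropped from both outcome models
  (`drop_excluded_sessions`, default yes).
* **Caffeine** is binarised at exactly 200 mg (one espresso) with ≥ semantics.
* **Normality gate:** `boxcox_if_needed()` runs a Shapiro–Wilk test and, only
  when p < 0.05, estimates the Box-Cox exponent by profile maximum likelihood
  on the grid λ ∈ [−5, 5] step 0.01 (log at λ = 0). Reaction-time data
  typically fail the gate and get λ near the log/inverse region; the transform
  is strictly increasing for every λ, so ranks are preserved. The fitted λ is
  kept in the result for reproducibility. For n > 5000 the test statistic uses
  a deterministic evenly spaced thinning (the test is defined to n = 5000).

# The inference layer

**Between-group comparisons** of activity outcomes use a classical one-way
ANOVA with partial eta squared from the sums-of-squares decomposition and all
pairwise pooled-variance t-tests, Bonferroni-corrected by the full family of
`choose(k, 2)` comparisons (10 for five groups) — the family definition is
stated because it is rarely reported.

**Cognitive outcomes** use a random-intercept linear mixed model,

```
outcome ~ time_of_day * chronotype + age + sex + caffeine + activity_prior_60min + (1 | participant)
```

fitted by REML (`lme4`), with time of day as continuous fractional hours since
midnight (no circular encoding: the observation window spans waking hours, and
the scientific question concerns a monotone trend across the day) and
chronotype as the continuous questionnaire total. Inference is Wald
normal-theory: estimate ± 1.96·SE and p from the z statistic, so an interval
excluding zero always coincides with p < 0.05 (a consistency the tests assert
for every term). No Satterthwaite/Kenward–Roger machinery is attempted; at the
design sizes involved (hundreds of observations, ~75 grouping levels) the
z approximation is adequate, and the simulation experiments below measure its
actual coverage rather than assuming it. Error counts are modelled as Gaussian
outcomes to match the linear-estimate reporting convention; this is a
pragmatic choice, adequate for counts averaging well above zero, and a Poisson
alternative would be the natural extension.

Fewer than two participants makes the random intercept unidentifiable; the
fit degrades to OLS with a warning (and the tests confirm the degenerate
coincidence with `lm()`).

# The synthetic cohort generator

The generator is first-class, tested code. Its defaults *are* the study
conditions the package targets:

* 75 participants, ages truncated-normal(25, 7²) on [18, 30], 57% female;
* latent chronotype uniform on [13, 55] — group sizes, not the score
  distribution, are published, and the uniform default populates all five
  quintiles; the range is configurable to match any empirical histogram;
* activity: cosinor (mesor 1500, amplitude ~N(1200, 300²) truncated at 0)
  clipped at zero, acrophase 14 h at the scale midpoint moving −0.1 h per
  CMQ point (earlier chronotypes peak earlier, between-person SD 0.5 h),
  plus ~1 Poisson-timed 30-min bout/day of magnitude 2000 and half-normal
  epoch noise (SD 500); per-day probability 0.05 of a 60–180 min zero-run
  non-wear gap, exercising the wear filter;
* sessions: targets 09:00/21:00 on days 1–6, Gaussian jitter (SD 20 min) plus
  0.5 min of lateness per CMQ point below 55 (later chronotypes test later);
* reaction times: shifted lognormal (shift 125 ms) whose *median* equals the
  linear predictor, trial-level SD 250 ms; the fixed-effect defaults are the
  reported XNA1 estimates (intercept 1195.21, time −15.65, chronotype −13.39,
  interaction +0.54, age 7.39, sex 12.15, caffeine 29.68, activity −3e−5),
  random-intercept SD 150 ms;
* a session-level mean-zero Gaussian state term (SD 100 ms) on top of the
  trial noise. Without it, a 44-trial session mean would carry implausibly
  little within-person error for home testing on a phone; the term stands in
  for sleep, environment and motivation fluctuating day to day;
* per-trial errors: Bernoulli with a logit-linear predictor mirroring the
  reaction-time signs.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: no raw 30-Hz signal, no sleep, no weekday/weekend or
social-jetlag structure, no practice effects across the six parallel task
versions, no RT–accuracy trade-off (correctness is independent of the drawn
RT), and independence of sessions given the random intercept and state term.
Recovery results below therefore validate the *estimator*, not the study's
substantive conclusions.

Determinism: each participant carries a derived seed, so any participant's
data can be regenerated in isolation, and a fixed configuration seed makes
every CSV byte-identical across runs.

# Simulation experiments

`recovery_experiment()` loops simulate → clean → assemble → fit and reports
per coefficient: truth, mean estimate, bias, empirical SD, Wald-CI coverage
and rejection rate. Two standing experiments (run in the test suite at 200
and 500 replicates, at the default study scale of 75 participants × 6
sessions) check that

* the interaction coefficient is recovered to within ±0.1 with CI coverage in
  [0.90, 0.98] and relative bias under 10% for the three headline terms
  (time, chronotype, interaction). A small attenuation is expected and
  observed: the model fits session *means* of a lognormal whose *median* is
  the linear predictor, which compresses slopes by a few percent — well inside
  the bias tolerance;
* with the interaction truth at zero, its test rejects at 3–7% — the nominal
  5% within Monte-Carlo error. The size experiment uses the *global* null
  (all slopes zero, intercept kept): zeroing only the interaction while
  keeping the large negative chronotype main effect would drive the
  generative reaction-time median below the 125 ms lognormal shift for early
  chronotypes late in the day — an incoherent data-generating process, which
  the generator correctly refuses to produce.

A further 20-seed experiment confirms the qualitative signatures: group mean
peak-activity time strictly increases from early to late chronotype groups,
and fitted trajectories converge towards the evening (the chronotype slope
`β_C + β_CT·t` shrinks in magnitude from 09:00 to 21:00).

`required_sample_anova_rm()` implements the repeated-measures between-groups
power calculation (noncentral F with λ = N·m·f²/(1 + (m − 1)ρ)). α, power and
the repeated-measures correlation are *explicit arguments* with conventional
defaults (0.05, 0.8, 0.5): such calculations are meaningless without them,
and published reports often omit them.

# Numerical choices and degenerate inputs

* Quintile ties go to the lower group (above); peak ties to the earliest
  window; the circular mean errors on a vanishing resultant (tolerance 1e−9).
* Rolling windows containing any missing epoch are missing, not partially
  summed; windows reaching before the series start are not emitted.
* Collinear fixed-effect designs fail loudly, naming the aliased columns;
  singular random-effect fits are flagged rather than hidden.
* Box-Cox requires strictly positive inputs and instructs the caller to
  supply a shift otherwise.
* The analysis table drops rows listwise on missing covariates, with one
  logged count per reason (`drop_log` attribute), so every exclusion count in
  a report can be reconstructed.

# Problem sizes

The test suite runs its oracle-equivalence checks on 100 random instances per
operation (series up to 2000 epochs, ANOVA instances up to 100 values), the
recovery experiment at 200 replicates and the type-I experiment at 500
replicates of the full 75 × 6 design, and the qualitative reproduction across
20 seeds. These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands (e.g. ±0.01 on a 5% rejection rate at 500 replicates) while
keeping a full run in the minutes range on a single core.

# Known limitations

* The shipped CMQ key is structural, not the published instrument; absolute
  scores are exact only for the true key, though the 13–55 bounds and all
  pipeline behaviour are key-independent.
* The non-wear heuristic is a stand-in for proprietary wear-detection
  algorithms; at 60-s epochs a genuine hour-long motionless rest is
  indistinguishable from non-wear.
* Gaussian modelling of error counts, Wald z inference, and the absence of an
  RT–accuracy coupling in the generator are pragmatic simplifications noted
  above.
* The power calculation treats only the between-groups effect of a
  repeated-measures design under compound symmetry.
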