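# chronocog

Tools for free-living studies of **chronotype, physical activity and
time-of-day cognition**. The package covers the full analysis chain such
studies need:

* **Chronotype** — scoring of the 13-item Composite Morningness Questionnaire
  (totals 13–55, higher = earlier chronotype), quintile group assignment
  (early … late), and the simple body-composition indices (BMI,
  waist-to-height ratio).
* **Actigraphy** — wrist-accelerometer 60-s epoch series: wear-time screening
  (< 90% wear excludes), trailing 60-min rolling AUC, daily peak-activity
  times with circular cross-day averaging, 7-day total activity, and the
  "activity in the previous hour" covariate.
* **Cognition** — cleaning of trial-level XNA task logs (XNA1: 17 trials,
  stimulus-oriented attending; XNA2: 27 trials, adding stimulus-independent
  attending and updating): 125/5000 ms reaction-time validity bounds, error
  counts, 8/10-error engagement exclusion, 200 mg caffeine binarisation, and a
  Shapiro–Wilk-gated Box-Cox transform.
* **Inference** — one-way ANOVA with Bonferroni post-hocs and partial η²
  between chronotype groups, and the central model: a random-intercept linear
  mixed model

  ```
  outcome ~ time_of_day * chronotype + age + sex + caffeine
            + activity_prior_60min + (1 | participant)
  ```

  with Wald 95% CIs, where the `chronotype × time-of-day` interaction carries
  the synchrony effect (late chronotypes worse in the morning, converging by
  evening).
* **Synthetic cohorts** — a generator producing complete studies
  (cosinor-plus-bouts actigraphy with chronotype-dependent acrophase, CMQ
  sheets that rescore to a latent chronotype, shifted-lognormal reaction
  times following the mixed-model linear predictor), enabling
  parameter-recovery and type-I-error validation of the whole pipeline
  without any raw data.

## Worked example

Simulate a default 75-participant study and run the whole pipeline:

```r
library(chronocog)
cfg <- simulation_config(rng_seed = 42L)
res <- run_pipeline(cfg, "demo_run")
print(res$fits$XNA1_rt)
```

```
Random-intercept LMM (rt, XNA1): 450 obs, 75 participants
                            term   estimate        se         ll         ul       t         p
1                    (Intercept)  1.074e+03 1.426e+02  7.944e+02  1.354e+03  7.5289 5.119e-14
2                  time_of_day_h -1.452e+01 3.229e+00 -2.085e+01 -8.194e+00 -4.4972 6.886e-06
3               chronotype_score -1.093e+01 2.123e+00 -1.509e+01 -6.769e+00 -5.1485 2.625e-07
4                            age  1.197e+01 5.349e+00  1.482e+00  2.245e+01  2.2371 2.528e-02
5                        sexmale  3.978e+01 4.111e+01 -4.079e+01  1.203e+02  0.9677 3.332e-01
6              caffeine_flagTRUE  4.191e+01 1.568e+01  1.118e+01  7.264e+01  2.6732 7.512e-03
7           activity_prior_60min -1.652e-04 2.766e-04 -7.074e-04  3.771e-04 -0.5970 5.505e-01
8 time_of_day_h:chronotype_score  4.568e-01 1.022e-01  2.566e-01  6.571e-01  4.4715 7.767e-06
Random intercept var = 21780.19, residual var = 11741.99
```

Reading the key rows: reaction times fall by ~15 ms per hour of the day
(`time_of_day_h`), each CMQ point of morningness is worth ~11 ms
(`chronotype_score`, negative = earlier chronotypes faster), and the positive
interaction (+0.46 ms per point·hour, p < 0.001) is the synchrony signature —
the chronotype gap shrinks as the day progresses. These estimates recover the
generative coefficients the simulation used (−15.65, −13.39, +0.54) within
their standard errors.

Activity timing separates the groups the same way:

```r
print(res$anova$peak_time)
```

```
One-way ANOVA: F(4, 70) = 19.555, p = 7.69e-11, partial eta^2 = 0.528
   group_i            group_j               raw_p bonferroni_p
 1 late               late_intermediate  7.25e- 2     7.25e- 1
 2 late               neutral            6.89e- 4     6.89e- 3
 3 late               early_intermediate 3.85e- 8     3.85e- 7
 ...
```

i.e. mean daily peak-activity time differs strongly between chronotype
groups, early groups peaking earliest.

Simulation-based validation of the estimator itself:

```r
rec <- recovery_experiment(simulation_config(), n_replicates = 200, seed = 1)
rec   # per-coefficient truth, bias, empirical SD, CI coverage, rejection rate
```

See `vignettes/chronocog-methods.Rmd` for the model, every convention
(window alignment, tie rules, circular averaging, non-wear heuristic) and the
design decisions behind the synthetic generator.

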