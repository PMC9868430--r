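# sowactivity

Analysis of high-frequency peripartum sow activity and its association with
piglet survival and early growth.

Loose-housed farrowing systems make sow behaviour a first-order determinant
of piglet outcomes: restless sows crush and starve more piglets, and sows
that hide their udder interrupt nursing. Video-based posture classifiers now
produce one posture label per sow every 5 seconds over the whole peripartum
window (D-3..D7 around farrowing), and this package implements the complete
statistical chain for such streams, for ethologists and animal-breeding
researchers:

* **Daily behavioural traits** from raw tick streams: despiking of
  single-observation runs, merging of confounded classes, daily postural
  and standing-activity time budgets, and three restlessness counts —
  PCAll (all posture changes), PCRiskCrush (standing→lying and
  sternal→lateral descents), PCStopNurse (udder-hiding transitions
  LLU→other).
* **Compositional clustering of activity patterns**: budgets are
  compositions, so they are mapped by an isometric log-ratio (ILR)
  transform, `y = V log x` with `V` an orthonormal balance basis, and
  clustered by k-means — cross-sectionally on the farrowing day,
  longitudinally (joint Euclidean distance on the flattened
  days × coordinates trajectory) on the multi-day periods, with elbow
  selection of k.
* **A three-step association protocol**: per-period single-variable
  screening with AIC choice between continuous and tertile (I/M/S) coding,
  per-period backward elimination by likelihood-ratio test, then a global
  cross-period model — applied to piglet survival via Cox proportional
  hazards, `h(t|x) = h0(t) exp(x'b)` with Efron tie handling (HR = exp(b),
  and (1−HR)·100 is the percent change in the instantaneous risk of
  dying), and to growth via OLS on the average daily gain
  ADG = (weight_D7 − birth weight)/7. Kaplan-Meier curves with log-rank
  tests and Schoenfeld-residual PH checks are included.
* **A calibrated synthetic cohort generator** (semi-Markov posture process
  with exchange rates `q_ij = rho·pi_j·M_ij`, per-day restlessness
  multipliers peaking at D-1, breed and sow heterogeneity in ILR space,
  and a discrete-time proportional-hazards piglet mortality model), so the
  whole pipeline is testable without any recordings.

## Worked example

```r
library(sowactivity)

cfg <- sim_config(n_sows = 60, seed = 7)        # calibrated defaults
coh <- build_cohort(cfg, return_streams = FALSE)
coh
#> sow_cohort: 60 sows, 660 sow-days of traits, 967 piglets (0 dropped days)

# farrowing-day quiescence: fraction of D0 spent lying
tr <- coh$traits
round(100 * mean(rowSums(tr[tr$day == 0, c("p_SL", "p_LL", "p_LLU")])), 1)
#> [1] 91.9

# cluster the two budgets per period, then run the association protocol
cl <- cluster_budgets(coh$traits, ks = 1:4, n_init = 20, seed = 7)
d  <- prepare_association_data(coh, cl$labels)
surv <- three_step_selection(d, "survival")
surv
#> Three-step survival selection: 2 behavioural term(s) retained
#>    post_cl_af, PCAll_af100

fit <- surv$final
fit$coefficients[fit$coefficients$term == "PCAll_af100",
                 c("term", "hr", "hr_lo", "hr_hi", "p")]
#>         term        hr    hr_lo     hr_hi            p
#>  PCAll_af100 0.4695846 0.364313 0.6052755 5.322267e-09
hazard_ratio_to_pct(0.56)
#> [1] 44
```

The retained count term says piglets of sows with more posture changes per
day after farrowing (per 100 changes) had a lower instantaneous risk of
dying; `hazard_ratio_to_pct()` converts any hazard ratio to the percent
risk change (an HR of 0.56 is a 44% reduction). At 60 sows the estimate is
still noisy — the planted generator effect is HR 0.56, and recovery
tightens to [0.50, 0.62] at 300 sows (see the acceptance script). `run_pipeline()`
chains simulate → extract → cluster → associate → report with CSV/JSON
artifacts and a seed/config-hash log; `report()` renders the cluster
composition and model tables.

## Documentation

The methods vignette (`vignettes/sow-activity-methods.Rmd`) describes the
models and their assumptions, every calibration choice of the synthetic
generator, the numerical conventions, and the protocol's measured
operating characteristics.
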