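---
title: "Peripartum sow activity patterns: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peripartum sow activity patterns: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowactivity)
```

## The scientific problem

Piglet survival and early growth in loose farrowing pens depend on how the
sow behaves around farrowing: restless sows crush or starve more piglets,
sows that hide their udder interrupt nursing, and pre-farrowing activity
(nest building) predicts maternal quality. Modern computer-vision systems
deliver a posture label every 5 seconds for every sow over the whole
peripartum period, which turns the question into a longitudinal,
compositional, and survival-analytic one. This package implements the full
analysis chain for such data:

1. **Stream cleaning and daily traits** — despiking of single-observation
   posture runs, class merging, daily postural and standing-activity time
   budgets, and three daily restlessness counts (`PCAll`, all posture
   changes; `PCRiskCrush`, standing-to-lying and sternal-to-lateral
   descents; `PCStopNurse`, transitions out of udder-exposed lateral
   lying).
2. **Compositional clustering** — isometric log-ratio (ILR) transformation
   of the daily budgets, then k-means: cross-sectionally on the farrowing
   day, longitudinally (joint Euclidean distance over the flattened
   day-by-coordinate trajectory) on the multi-day periods, with the elbow
   rule for the number of clusters.
3. **Association protocol** — a three-step variable selection linking sow
   behaviour to piglet survival (Cox proportional hazards, Efron ties) and
   growth (OLS on average daily gain D0–D7), with Kaplan-Meier and
   Schoenfeld-residual diagnostics.
4. **A calibrated synthetic cohort generator**, so that every stage is
   testable end to end without access to any real recordings.

The ethogram has six postures — standing (ST), sitting (SI), kneeling (K),
sternal lying (SL), lateral lying (LL) and lateral lying with the udder
exposed (LLU) — and three standing activities (eating, drinking, other).
Days are indexed relative to farrowing (D-3..D7, D0 being the 24 h after
the first birth) and grouped into three periods: before farrowing
`bf` = D-3..D-1, the farrowing day `df` = D0, after farrowing `af` = D1..D7.

## Stream cleaning

Single-tick posture runs are treated as classifier errors and replaced by
the posture of the previous observation. Two details are fixed by
convention because the rule's verbal statement underdetermines them:

* Singleton runs are identified on the **raw** stream and the pass is
  causal (left to right), so the replacement value is read from the
  *evolving* output — a chain of adjacent singletons collapses onto the
  last surviving posture. A singleton at the very start of a sow-day has
  no previous observation and is kept.
* The activity label of a replaced tick is copied together with the
  posture, so the "activity only while standing" constraint can never be
  violated by cleaning.

The extraction order is fixed: despike, then merge sitting and kneeling
(the two visually confounded, low-precision classes) into `SIK`, then
compute budgets and counts. Merging first can hide genuine singletons (two
different raw labels mapping to one class) and is rejected by a test. The
three counts are computed after merging; `count_posture_changes()` itself
works on any labelled stream, so the opposite convention is one call away.

## Compositional analysis

Daily budgets are compositions (they close to 1), so Euclidean operations
on raw proportions are not meaningful. Both budgets are mapped to
unconstrained coordinates with an ILR transform built from a sequential
binary partition: for the postural budget, lying vs non-lying first, then
udder-exposed vs hidden lying, sternal vs lateral, standing vs
sitting/kneeling; for the standing-activity budget, maintenance
(eat + drink) vs other, then eat vs drink. Because every orthonormal basis
of the simplex differs from any other by a rotation, and k-means uses
Euclidean distance, cluster assignments are basis-invariant (a test
asserts this); the choice of partition only affects how interpretable the
individual coordinates are.

Zeros (a sow that never stood on some day has an undefined or zero-valued
budget entry) are handled by multiplicative replacement with
`delta = 1/(2 * 17280)` — half of one tick's share of a day, i.e. "less
than the smallest observable amount". A day with *no* standing tick at all
is treated as a missing activity budget, not as a zero composition, and
excludes that sow from the activity clustering of that period.

Longitudinal clustering of the `bf` and `af` periods uses the joint
Euclidean distance over the flattened days-by-coordinates array, which is
exactly k-means on the flattened matrix (asserted by a definitional test).
The k sweep uses 50 random restarts per k plus, for k+1, an
initialization derived from the best k-solution (its centers plus the
worst-fitted point), which guarantees a non-increasing inertia profile;
the elbow rule then picks the interior k with the largest second
difference, breaking ties toward the smaller k. No per-coordinate
standardization is applied before clustering: ILR coordinates already
share a scale. Cluster letters A, B, C are assigned by descending size.

## The synthetic cohort generator

No public recordings exist, so the generator is a first-class module and
defines the study conditions for all recovery experiments.

**Posture process.** Each sow-day is a continuous-time Markov jump process
over the six postures, discretized to 5-s ticks. Jump rates factor as
`q_ij = rho * pi_j * M_ij` with a symmetric pair-affinity matrix `M`; by
detailed balance the stationary distribution is exactly the target budget
`pi` for *any* positive `M`, which cleanly separates the two calibration
surfaces:

* `pi` per period sets the time budgets — before farrowing ~21% standing
  and 77% lying; on the farrowing day 92% lying; after farrowing 89%
  lying, dominated by udder-exposed lateral lying;
* `rho` and `M` set the pace and the *composition* of posture changes.
  `rho` is chosen so the expected daily change count matches the published
  per-day means (220, 297, 470, 282, 247, 257, 219, 241, 236, 266, 253
  for D-3..D7 — restlessness peaks the day before farrowing), and the
  per-day multiplier carries that profile within each period. The pair
  affinities are solved per period so the expected *shares* of
  nursing-stop and crushing-risk transitions match their own published
  daily means; without this, a destination-proportional kernel makes ~85%
  of all transitions involve the dominant LLU state and the three counts
  become mechanically collinear.

**Heterogeneity.** Between-sow variation enters on three orthogonal axes,
all fixed a priori: a lognormal restlessness multiplier (sdlog 0.5) and a
lognormal day-to-day jitter (sdlog 0.25), which together reproduce the
published dispersion of daily counts (CV ≈ 0.6); Gaussian noise in ILR
space (sd 0.15 per coordinate) on the stationary budget, with breed shifts
added in the same space (Large White sows lean toward udder-exposed lying
before farrowing, Meishan toward plain lateral lying, mirroring the
reported breed-pure pre-farrowing clusters); and two lognormal
*transition-style* propensities (sdlog 0.4) that multiply the pair
affinities of the LLU pairs (nursing interruption) and of the
standing/sternal descents (descent style). The style propensities
reallocate which transitions a sow uses at a fixed overall pace and leave
her budget untouched; they are what makes the three daily counts
statistically distinguishable across sows, as they visibly are in real
data where the counts have different coefficients of variation. Activities
are drawn per standing bout from a per-sow distribution (ILR-space noise,
sd 0.25 per coordinate, around period means of roughly 27% eating and 21%
drinking).

Realized daily counts run some 10–20% below the nominal calibration
because despiking and 5-s discretization absorb very short dwells; the
calibrated *shape* (the D-1 peak, the period shares) is unaffected, and
the day-of-farrowing lying fraction is reproduced within a percentage
point.

**Piglet outcomes.** Litters are uniform on 12–21 piglets with a mixed
Large White/Meishan sire draw per piglet (four genetic types). Death days
follow a discrete-time proportional-hazards model on days 1..28 with a
per-day baseline hazard of 0.0055 (≈ 13–14% cumulative mortality) and a
log-hazard linear in configured sow covariates; covariates are centred at
their cohort mean so the baseline describes an average sow's piglet and
overall mortality does not drift with the planted effect size. The default
planted effect is a hazard ratio of 0.56 per 100 daily posture changes
after farrowing. Weights follow `birth weight + ADG * day`, with birth
weights per genetic type (875–1292 g) and ADG built from an intercept of
229.5 g/d, genetic-type, pen and litter-size-class shifts, planted
superior-tertile shifts for three sow traits (−22.37 g/d for restless
sows before farrowing, −45.33 g/d for frequent nursing-stops on D0,
+70.84 g/d for frequent nursing-stops on D1–D7) and a 50 g/d residual.
Piglets dead before a weighing day have that weight missing, which is what
removes them from the growth model (ADG needs the D7 weight).

Sub-seeds are derived per sow from the master seed, so enlarging a cohort
never perturbs the streams of existing sows. Survival times have whole-day
resolution (deaths are found at the morning inspection), which produces
heavy ties — the reason the Cox fits use the Efron correction throughout.

## The three-step association protocol

All models include the fixed effects of piglet genetic type (4 levels),
litter-size class (12–14, 15–16, 17–21 born alive) and pen (A–D); these
are never dropped.

**Step 1** screens each period-eligible behavioural item one at a time
next to the fixed effects. Count items are tried as continuous and as
I/M/S tertile classes (growth models also try the binary S vs M+I
collapse); the coding with the lower AIC is kept, and the item survives if
the likelihood-ratio test against the fixed-effects-only model gives
p < 0.05. Tertiles are computed on the per-dam distribution (type-7
quantiles at 1/3 and 2/3) with `I` for values at or below the lower cut
and `S` strictly above the upper cut. Significant cluster items are
additionally compared by AIC against the raw budget trait that best
separates the cluster centres (largest range of cluster means in units of
the trait's SD — a declared convention). Before farrowing only the two
pattern variables and `PCAll` are tested; `PCStopNurse` is not tested on
D0 for survival; growth analyses use `PCAll` and `PCStopNurse` but not
`PCRiskCrush`.

**Step 2** fits the per-period saturated model and removes, one at a time,
the term whose removal gives the largest LRT p-value while that p-value
exceeds 0.05 (ties broken by the smaller |coefficient|/SE). **Step 3**
pools the survivors of the three periods and repeats the elimination;
collinear cross-period duplicates are dropped first and recorded. The full
sequence of decisions is kept as a replayable trace.

One operating characteristic deserves honesty: the *per-coding* screening
test has its nominal 5% size (measured 5.0% for the continuous coding over
1000 null replicates), but because step 1 picks the better-fitting coding
by AIC *before* testing, the per-candidate screen is mildly
anti-conservative (~10% for a pure-noise candidate with two codings
available). This is inherent to the protocol's choose-then-test design,
not to the implementation; the acceptance suite therefore checks the size
of the screening test at a fixed coding and the package documents the
union rate rather than hiding it.

Piglet-level models with dam-level covariates ignore litter clustering by
default (none is described in the protocol being implemented); a robust
sandwich SE clustered by dam is available via `cox_fit(..., cluster =
"dam_id")` for sensitivity analyses.

## What the tests do and do not show

The test suite verifies the machinery against independent oracles
(brute-force transition scanning, grid-search partial-likelihood
maximization, normal-equations solves, closed-form ILR values) and
verifies *recoverability* on the calibrated synthetic cohort: a planted
HR of 0.56 per 100 posture changes is recovered within [0.50, 0.62] at
~300 sows, the three planted growth shifts within 2 SE, planted 91% vs
80% udder-exposed regimes with adjusted Rand index > 0.8, and the
selection retains the planted terms. Because the generator is a
semi-Markov caricature — exponential dwell times, no nursing-bout
microstructure, no diurnal rhythm, no real classifier confusion structure
— passing these tests demonstrates correctness and statistical power of
the *pipeline*, not fidelity of any particular biological conclusion to
new data. Problem sizes in the routine suite (cohorts of 3–80 sows for
unit tests, 300 sows for recovery, 400 replicates for size checks) were
chosen as the smallest that leave the Monte-Carlo error well inside the
asserted bands.

## Numerical and degenerate-input conventions

* Budgets close to 1 within 1e-12; ILR round-trips are exact to 1e-10.
* `zero_replace()` requires `delta` below the smallest non-zero part.
* A rate matrix with a negative entry is rejected; an all-zero rate
  process is a valid absorbing chain (constant posture).
* `k = n` clustering yields zero inertia; `k > n` is an error; k-means
  ties in the elbow rule resolve toward smaller k, label ties by the
  lexicographic order of centre coordinates.
* Cox fits refuse event-free data and rank-deficient designs with
  explicit errors; monotone-likelihood warnings from tiny instances are
  surfaced, not suppressed.
* Missing sow-days are encoded by absence; a sow is excluded from a
  period's clustering if any day of that period is missing, and from the
  activity clustering also when any day has no standing tick.
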