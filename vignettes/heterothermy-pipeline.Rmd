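---
title: "From PIT-tag read streams to hyperthermia models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PIT-tag read streams to hyperthermia models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swallowtherm)
```

## The scientific problem

Chick-rearing swallows commute between foraging flights and a nest box
all day. Flight generates metabolic heat; on warm days that heat is hard
to shed, and a provisioning female faces a choice between slowing down
(anticipatory regulation) and letting her body temperature rise above
normothermic levels for a while (facultative hyperthermia). A
thermal-sensitive PIT tag under the skin, read by an antenna around the
box entrance, gives a body-temperature (Tb) sample every time the bird
is at the box — an irregular, presence-biased time series. This package
turns such read streams into the quantities the field's analyses are
built on, and fits those analyses:

1. **Visits** — contiguous runs of reads (gap threshold 120 s by
   default; the tag re-read delay is 10 s, so anything above that is a
   design choice, and the threshold is exposed). Visits of at least
   5 minutes (boundary inclusive) count as **resting** bouts.
2. **Thermal profile per bird** — the modal resting Tb (0.1 °C bins,
   ties broken toward the lower bin), the heterothermy index
   \(HI = \sqrt{\sum_i (T_{mod} - T_{b,i})^2 / (n-1)}\)
   over the same resting observations, and the individual
   **hyperthermia threshold** \(T_{mod} + HI\). An observation is
   hyperthermic when Tb is *strictly above* the threshold.
3. **Bird-hour table** — for every bird and clock hour with at least
   one read: total and hyperthermic observation counts, their
   proportion, mean Tb, per-chick feeding rate (visit starts per hour
   divided by brood size), ambient temperature and covariates.
4. **Filters** — nestling days 3–14, clock hours 05–20 (data spanning
   05:00–21:00), ambient temperature at most 30.9 °C (the boundary kept),
   and an aberrant-day screen (below).
5. **Models** — a weighted polynomial linear mixed model for hourly Tb;
   a Welch t-test on thresholds; and a two-part (hurdle) analysis of
   hyperthermia frequency: a binomial mixed model for whether any
   hyperthermia occurred within an hour, and a Tweedie mixed model for
   the hyperthermic proportion within hours where it did.

## The body-temperature model

`fit_lmm_tb()` fits, with a random intercept per bird,

mean hourly Tb ~ treatment + poly(Ta, k) + feeding rate + nestling age +
maternal age + hour + brood size + treatment:poly(Ta, k) +
treatment:feeding rate

* **Polynomial order** k ∈ {1, 2, 3} is selected by likelihood-ratio
  tests between ML fits (`lr_test()`), with AIC (`model_aic()`,
  `2k − 2logL`) reported alongside; REML is used for the reported
  coefficient table. Parameter counts include the two variance
  components, so the linear/quadratic/cubic models have 12/14/16
  parameters.
* **Orthonormal polynomial coding** (`stats::poly`) is the default: the
  columns are mutually orthonormal over the sample, which keeps the
  Ta¹–Ta³ estimates on a comparable near-unit scale and makes the order
  selection well conditioned. Raw powers are available via
  `raw_poly = TRUE`; note that the orthonormal basis is
  sample-dependent, so coefficient values (not fits) change with the
  sample.
* **Weights**: observations are weighted by the inverse variance of
  feeding rate, computed per bird by default (heteroskedasticity:
  feeding-rate variability shrinks as rates rise); an hour-of-day
  grouping and unweighted fits are available. Weights are normalized to
  mean one.
* **Inference** is Wald throughout: CIs are estimate ± 1.96·SE and the
  statistics are z-scores. With 16 birds these intervals are slightly
  optimistic for bird-level effects (a t reference with ~14 df would be
  wider); this is a deliberate, documented convention of the whole
  package, not an oversight.

## The two-part hyperthermia model

Hour-level hyperthermia data are dominated by zeros. A single
zero-inflated model of the proportion has poor predictive power here,
so the analysis splits into:

* `fit_any_hyper()` — logistic random-intercept model (Laplace ML via
  glmmTMB) of "at least one hyperthermic observation this hour", with
  treatment, Ta, feeding rate, nestling age, maternal age, hour, the
  bird's threshold, and treatment × Ta. Apparent complete separation
  (|log-odds| > 15) is flagged, never silent.
* `fit_prop_hyper()` — for the positive hours only, a Tweedie
  (power-variance, log link) random-intercept model of the proportion.
  The variance power is fixed at 1.5 — the midpoint of the
  compound-Poisson range, matching the event-like structure of the
  data (a few excursions of variable length per hour) — and can be
  fixed elsewhere in (1, 2) or estimated. A true Tweedie GLMM is used
  rather than a quasi-likelihood approximation with bird offsets,
  because the estimation machinery for the exact model exists and is
  standard in this field. Residual serial correlation within birds
  beyond the random intercept is *not* modelled; the hour-level
  dependence induced by heat carry-over means the reported SEs for this
  sub-model should be read as mildly optimistic (we measure 95% CI
  coverage of ~80–85% for bird-level terms under the null in
  simulation).

`marginal_predictions()` produces population-level predictions on a
reference grid with delta-method Wald intervals, optionally averaged
over grid cells.

## The aberrant-day screen

Field datasets of this kind occasionally contain a bird-day whose
morning Tb runs ~2 °C low — a tag/placement artefact. The screen
operationalizes the visual check used in practice: for each bird-day,
the index is the **upper quartile of the early-morning readings**
(05:00–10:00), compared against the mean index over the bird's other
days; a deficit of at least 1.25 °C flags the day, and the whole
bird-day is removed. The upper quartile is used because a plain morning
mean swings with how much of the morning the bird spent resting (Tb at
rest is lower and more variable), and the early-morning window avoids
late-morning heat; both choices were validated against injected
artefacts (sensitivity 1.0, false-positive rate 0.1% over 30 simulated
colonies at the defaults). Days with fewer than 20 in-window readings
neither get flagged nor enter the baseline — a shifted day cannot be
distinguished from noise with a handful of reads. All thresholds are
arguments.

## What the simulator emulates

`simulate_campaign()` generates a complete field campaign with known
ground truth: 16 females (8 control, 8 with ventral feathers trimmed to
increase heat-dissipation capacity), nestling days 0–14, hatch dates
spread over 10 days, an hourly ambient series (seasonal mean + day
effects + diurnal sinusoid + noise; daytime daily means ≈ 21 ± 5 °C),
three ~24 h reader-coverage windows per nest (early/middle/late
provisioning), and the 10 s tag re-read delay, enforced globally by the
emulated reader.

The latent thermal model is a linear heat-balance, not a biophysical
simulation — the claims being tested concern distributional signatures,
not mechanism:

* Visits follow an inhomogeneous Poisson process; the rate per chick
  declines with Ta above a pacing threshold for control birds
  (anticipatory regulation), with hour-level workload noise for both
  groups so that feeding rate remains statistically identifiable
  alongside the Ta terms.
* Each foraging trip deposits a lognormally variable heat pulse that
  grows with Ta; heat decays slowly between visits (flight), moderately
  during short sits, and fast once a bird commits to a resting bout
  (postural heat dump). Trimming scales the *flight* cooling constant
  (the exposed brood patch sheds heat into the airstream).
* Facultative hyperthermia appears as stored-heat excursions whose
  probability rises with heat load and with hot air, and whose
  magnitude and persistence scale with how poorly the bird dissipates —
  control birds have fewer but longer hyperthermic spells, trimmed
  birds brief ones. This is what makes the positive-part (Tweedie)
  treatment effect strongly negative while pooled hyperthermic
  fractions differ only moderately, the combination the field data
  show.
* At rest, Tb either sits tightly at the bird's modal value or wanders
  downward (rest-phase heterothermy). The downward-only wander is what
  gives resting birds a heterothermy index of ~1.5 °C without creating
  spurious hyperthermia, and it leaves the modal bin sharp: modal-Tb
  recovery is within one 0.1 °C sensor bin for ~90% of birds (worst
  cases 2–3 bins, from excursion-contaminated resting bouts in birds
  with few bouts).
* Trimmed birds get a small capped compensatory Tb elevation at low Ta
  while active (insulation loss), which reproduces the observed
  crossing of the treatment Tb curves at the cold end.

Simulated campaigns at the default parameters land at: pooled
hyperthermic fractions ≈ 13% (control) vs ≈ 11% (trimmed), mean hourly
Tb ≈ 42.0 °C, HI ≈ 1.5 °C, resting bouts ≈ 7% of visits, ~40 000 reads
per campaign. What passing tests on these campaigns do **not** show:
the simulator has no weather–site structure, no male provisioning, no
nest microclimate, no energy or water budget, and its residual
correlation structure is simpler than a real logger's — so parameter
recovery here demonstrates that the pipeline estimates what the
generating model encodes, not that the field estimates are right.

## Numerical and design choices

* Timestamps are local civil time handled in a DST-free frame; all
  text round trips are exact (full-precision numeric formatting).
* Mode binning at 0.1 °C (the sensor's reporting resolution); ties go
  to the lower bin — the conservative direction, since a lower
  threshold flags *more* hyperthermia.
* A single isolated read is a zero-duration visit (observable span
  only) and can never be resting.
* Reads belong to the clock hour containing their timestamp; hourly
  mean Tb is the plain mean of reads (reads are near-uniform at 10 s
  while present, so duration weighting would change little).
* "05:00 to 21:00" is the half-open interval [05:00, 21:00): hour bins
  5 through 20.
* Brood size queried for nestling days 13–14 returns the day-12 value
  (nests are not visited later).
* The problem sizes used by the test-suite simulation studies — 200
  seeded campaigns for effect recovery, 150 for null CI calibration,
  30 colonies for the filter audit — were chosen to pin Monte-Carlo
  error on the reported rates to a few percent.

## Known limitations

* Brooding and resting cannot be distinguished from reader data; the
  resting-bout definition includes brooding females by construction.
* Wald/z inference everywhere; no Satterthwaite or Kenward–Roger df
  corrections, and no AR(1) residual structure in the positive-part
  model (see above for the measured consequence under the null).
* The positive-part model conditions on hours with observed
  hyperthermia; its likelihood treats the zero-truncated response with
  an untruncated family, as is common practice for this two-part
  design.
* With 8 birds per treatment, between-group contrasts of mean Tb carry
  the sampling luck of the birds' baseline temperatures; effects
  expressed through interactions (treatment × Ta², the positive-part
  treatment effect) are recovered far more reliably than level
  contrasts, and single-campaign level contrasts should not be
  over-read.
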