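# swallowtherm

Body-temperature regulation in chick-rearing birds, from raw
thermal-PIT-tag read streams to the statistical models of heterothermy
and facultative hyperthermia.

Provisioning swallows shuttle between foraging flights and the nest box
all day; flight generates heat, and on warm days a female must either
slow down (anticipatory regulation) or let her body temperature (Tb)
rise above normothermic levels for a while (facultative hyperthermia).
Field studies probe this with subcutaneous thermal PIT tags read by an
antenna at the box entrance, plus an experimental manipulation —
trimming the ventral feathers of half the females to increase their
heat-dissipation capacity. This package implements that entire analysis
as tested, reusable code, for thermal ecophysiologists working with
RFID/PIT biologging data:

* **Event stream** — segments tag reads into nest-box visits (gap
  threshold, default 120 s), flags resting bouts (>= 5 min, boundary
  inclusive), and computes hourly per-chick feeding rates.
* **Thermal metrics** — per bird: modal resting Tb (`T_mod`, 0.1 °C
  bins, ties to the lower bin), the heterothermy index

      HI = sqrt( sum_i (T_mod − T_b,i)^2 / (n − 1) )

  over resting observations, and the hyperthermia threshold
  `T_mod + HI`; a reading is hyperthermic when it *surpasses* the
  threshold (strictly greater).
* **Filters** — nestling days 3–14, hours 05–20, ambient temperature
  <= 30.9 °C, and a screen for aberrant bird-days (a morning running
  ~2 °C low is a tag artefact).
* **Models** — inverse-variance-weighted polynomial linear mixed model
  for hourly Tb with likelihood-ratio/AIC order selection (lme4); Welch
  t-test on thresholds; and a two-part hyperthermia analysis: binomial
  mixed model for any-hyperthermia-per-hour and a Tweedie
  (power-variance, p = 1.5) mixed model for the hyperthermic proportion
  in positive hours (glmmTMB).
* **Synthetic biologger** — a full campaign simulator (weather, nests,
  reader schedules with the 10 s re-read delay, visit behaviour, latent
  heat-balance Tb dynamics, facultative-hyperthermia excursions) with
  known ground truth, so every stage is testable without field data.

## Worked example

```r
library(swallowtherm)

camp <- simulate_campaign(sim_config(), seed = 42)   # 16 birds, ~40k reads
res  <- analyze_campaign(camp$reads, camp$weather, camp$nests)
report_summary(res)
```

```
Pooled hyperthermic observations by treatment:
# A tibble: 2 × 4
  treatment n_obs n_hyper pct_hyper
  <chr>     <int>   <int>     <dbl>
1 control   15175    2221     14.6
2 trimmed   17732    1555      8.77

Mean modal Tb, HI and hyperthermia threshold by treatment:
  treatment mean_t_mod mean_hi mean_threshold
1 control         41.0    1.42           42.4
2 trimmed         41.2    1.49           42.7

Treatment effect, positive-part (Tweedie) hyperthermia model:
  term             estimate std_error ci_lower ci_upper statistic p_value
1 treatmenttrimmed   -0.395     0.246   -0.877   0.0865     -1.61   0.108
```

Reading this: of all control-bird readings, 14.6% exceeded the bird's
own threshold (modal resting Tb + HI), versus 8.8% for birds with an
experimentally increased capacity to dissipate heat — trimmed birds
resort to storing heat less often. Their thresholds themselves are
similar (42.4 vs 42.7 °C), and within hours where hyperthermia occurred
at all, trimmed birds spent a smaller proportion of the hour
hyperthermic (the negative treatment effect on the log scale). The Tb
model's polynomial order is chosen by likelihood-ratio tests:

```r
res$models$aic
#        model log_likelihood n_parameters  aic
# 1 tb_lmm_ta1         -707.1           12 1438
# 2 tb_lmm_ta2         -653.6           14 1335
# 3 tb_lmm_ta3         -634.3           16 1301
```

— the cubic Ta model wins, mirroring the nonlinear Tb–Ta relationship
seen in the field.

The same pipeline runs against files on disk (`run_pipeline()`, or the
CLI in `inst/scripts/swallowtherm-cli.R` with verbs `simulate`,
`analyze`, `all`), writing the bird-hour table, thermal profiles, model
coefficient tables, filter reports and a reproducible run manifest;
reruns with the same seed are byte-identical.

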