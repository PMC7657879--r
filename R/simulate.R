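#' Simulation configuration
#'
#' Defaults describe a two-treatment field campaign on 16 PIT-tagged
#' chick-rearing females (8 control, 8 feather-trimmed), nestling days
#' 0--14, with three ~24 h reader-coverage windows per nest (early days
#' 2--5, middle 6--9, late 10--14), a 10 s tag re-read delay, and a
#' temperate early-summer weather regime whose daytime (05:00--21:00)
#' daily means average about 21 deg C with s.d. about 5 deg C.
#'
#' The latent body-temperature model is a discrete-time linear
#' heat-balance: each foraging trip deposits a heat pulse (larger when the
#' air is warm) that decays exponentially with a cooling time constant;
#' trimmed birds cool faster (`dissipation_multiplier` < 1 scales their
#' time constant down). Control birds pace: their visit rate declines
#' above `pacing_threshold`. Occasional regulated excursions add to heat
#' load with a probability that is logistic in the current load.
#'
#' @param n_birds Number of females (half per treatment).
#' @param days Last nestling day simulated.
#' @param hatch_spread Days between the first and last hatch date.
#' @param ta_mean Seasonal mean of the hourly ambient series, deg C.
#' @param ta_diurnal_amplitude Amplitude of the diurnal sinusoid, deg C
#'   (peak at 15:00).
#' @param ta_day_sd Day-to-day s.d. of the daily mean, deg C.
#' @param ta_noise_sd Hourly noise s.d., deg C.
#' @param base_visit_rate Visits per hour per chick below the pacing
#'   threshold.
#' @param pacing_threshold Ta above which control birds slow down, deg C.
#' @param pacing_slope Fractional rate reduction per deg C above the
#'   threshold (control birds only).
#' @param pacing_floor Minimal fraction of the base rate.
#' @param pacing_noise_sd Hour-to-hour s.d. of the rate multiplier
#'   (workload variation unrelated to weather), both treatments.
#' @param resting_prob Probability that a visit is a long resting/brooding
#'   bout.
#' @param rest_settle_prob Probability that a resting-bout read sits
#'   tightly at the bird's modal Tb; with the complementary probability
#'   the read wanders (rest-phase heterothermy).
#' @param rest_wander_mean,rest_wander_sd Distribution of the wandering
#'   deviation at rest, deg C; the negative mean encodes the regulated
#'   relaxation of Tb below the modal value while inactive, which is what
#'   gives resting birds a heterothermy index much larger than sensor
#'   noise without inflating hyperthermia.
#' @param visit_mean_duration Mean duration of ordinary visits, s.
#' @param resting_duration_range Range of resting-bout durations, s.
#' @param tmod_mean,tmod_sd Across-bird distribution of the true resting
#'   modal Tb, deg C.
#' @param ta_coupling Passive Tb drift per deg C of Ta.
#' @param heat_increment Mean heat pulse per foraging trip at cool Ta,
#'   deg C.
#' @param heat_increment_slope Fractional pulse increase per deg C above
#'   `heat_knee`.
#' @param heat_pulse_sdlog Log-scale s.d. of the per-trip pulse
#'   (lognormal, mean preserved): trip-to-trip variability in flight
#'   effort is what produces occasional threshold crossings at moderate
#'   heat loads without shifting the mean Tb curve.
#' @param heat_knee Ta knee for the pulse size, deg C.
#' @param cold_comp_slope Compensatory Tb elevation per deg C below
#'   `cold_comp_knee` for trimmed birds only: with part of their
#'   insulation removed they must produce extra heat in the cold, so at
#'   low Ta their Tb sits slightly above controls'.
#' @param cold_comp_knee Ta below which the compensation engages, deg C.
#' @param cold_comp_cap Upper bound on the compensatory elevation, deg C.
#' @param cooling_tau Cooling time constant between visits (bird in
#'   flight, still producing heat), s, control birds.
#' @param sit_cooling_tau Cooling time constant during an ordinary short
#'   sit at the box entrance, s.
#' @param resting_cooling_tau Cooling time constant once a bird commits
#'   to a long resting/brooding bout (posture change, no exercise heat),
#'   s; bouts settle at the resting modal Tb within a couple of minutes.
#' @param rest_heat_dump Fraction of the arriving heat load still
#'   expressed after the postural dump at the start of a resting bout.
#' @param dissipation_multiplier Multiplier (0, 1] on the flight cooling
#'   time constant for trimmed birds (the exposed brood patch sheds heat
#'   into the airstream).
#' @param excursion_prob_intercept,excursion_prob_slope Logistic
#'   coefficients of the per-visit facultative-hyperthermia excursion
#'   probability in the current heat load.
#' @param excursion_ta_slope,excursion_ta_knee,excursion_ta_cap Extra
#'   logistic slope on ambient temperature above the knee, saturating
#'   `excursion_ta_cap` deg C higher: storing heat becomes the cheap
#'   strategy when the air is too warm to dump it.
#' @param excursion_amp_sdlog Bout-to-bout lognormal variability of the
#'   stored-heat magnitude (mean preserved).
#' @param excursion_amp_power Exponent on `tau / cooling_tau` scaling the
#'   stored-heat magnitude: a bird that dissipates well stores less.
#' @param excursion_persist_frac Controls how long a stored-heat
#'   excursion lasts: its decay time constant is
#'   `excursion_persist_frac * tau^2 / cooling_tau` for a bird
#'   with flight cooling constant `tau`, so trimmed birds shed stored
#'   heat disproportionately faster (brief spikes) while control birds
#'   stay elevated for most of a sit.
#' @param excursion_amp Extra heat during an excursion, deg C.
#' @param obs_noise_sd Sensor noise s.d., deg C (readings are then
#'   quantized to 0.1 deg C).
#' @param read_delay Seconds between successive reads of one tag.
#' @param coverage_hours Length of each reader window, h.
#' @param stages Named list of provisioning-stage day ranges.
#' @param start_date Hatch date of the earliest nest.
#' @return A named list of parameters (class `st_sim_config`).
#' @export
sim_config <- function(n_birds = 16,
                       days = 14,
                       hatch_spread = 10,
                       ta_mean = 19.4,
                       ta_diurnal_amplitude = 6,
                       ta_day_sd = 4,
                       ta_noise_sd = 0.8,
                       base_visit_rate = 2.4,
                       pacing_threshold = 22,
                       pacing_slope = 0.25,
                       pacing_floor = 0.15,
                       pacing_noise_sd = 0.15,
                       resting_prob = 0.06,
                       rest_settle_prob = 0.5,
                       rest_wander_mean = -1.7,
                       rest_wander_sd = 1.6,
                       visit_mean_duration = 35,
                       resting_duration_range = c(300, 900),
                       tmod_mean = 41.3,
                       tmod_sd = 0.8,
                       ta_coupling = 0.005,
                       heat_increment = 0.2,
                       heat_increment_slope = 0.8,
                       heat_pulse_sdlog = 0.8,
                       heat_knee = 22,
                       cold_comp_slope = 0.2,
                       cold_comp_knee = 18,
                       cold_comp_cap = 0.7,
                       cooling_tau = 900,
                       sit_cooling_tau = 90,
                       resting_cooling_tau = 30,
                       rest_heat_dump = 0.3,
                       dissipation_multiplier = 0.45,
                       excursion_prob_intercept = -1.5,
                       excursion_prob_slope = 0.3,
                       excursion_ta_slope = 0.15,
                       excursion_ta_knee = 24,
                       excursion_ta_cap = 3,
                       excursion_amp = 2,
                       excursion_amp_sdlog = 0.6,
                       excursion_amp_power = 1,
                       excursion_persist_frac = 0.3,
                       obs_noise_sd = 0.1,
                       read_delay = 10,
                       coverage_hours = 24,
                       stages = list(early = c(2, 5), mid = c(6, 9),
                                     late = c(10, 14)),
                       start_date = as.Date("2018-05-28")) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_birds >= 2, cfg$base_visit_rate > 0,
    cfg$dissipation_multiplier > 0, cfg$dissipation_multiplier <= 1,
    cfg$cooling_tau > 0, cfg$obs_noise_sd >= 0, cfg$tmod_sd >= 0,
    cfg$read_delay > 0
  )
  structure(cfg, class = "st_sim_config")
}

#' Simulate the hourly ambient-temperature series
#'
#' `ta(hour) = mean + day effect + diurnal sinusoid + noise`, one record
#' per clock hour, reproducible given the RNG state.
#'
#' @param config A [sim_config()].
#' @param n_days Number of days to simulate.
#' @param start_date First day (default from `config`).
#' @return Weather tibble (`hour_start`, `ta`).
#' @export
simulate_weather <- function(config, n_days = config$days +
                               config$hatch_spread + 2,
                             start_date = config$start_date) {
  day_eff <- rnorm(n_days, 0, config$ta_day_sd)
  hours <- 0:23
  hour_start <- as.POSIXct(
    rep(as.POSIXct(paste(start_date, "00:00:00"), tz = ST_TZ) +
          86400 * (seq_len(n_days) - 1), each = 24) + 3600 * hours,
    tz = ST_TZ)
  ta <- config$ta_mean +
    rep(day_eff, each = 24) +
    config$ta_diurnal_amplitude * cos(2 * pi * (rep(hours, n_days) - 15) / 24) +
    rnorm(n_days * 24, 0, config$ta_noise_sd)
  tibble::tibble(hour_start = hour_start, ta = ta)
}

#' Simulate the nest/bird roster
#'
#' Builds the nest metadata for `n_birds` females: balanced treatment
#' groups, maternal ages in the field ratios (control 2 SY : 6 ASY,
#' trimmed 4 SY : 4 ASY, scaled to group size), hatch dates spread over
#' `hatch_spread` days, clutch sizes of 4--7 and brood sizes recorded on
#' nestling days 0--12.
#'
#' @param config A [sim_config()].
#' @return Nest metadata tibble (see [read_nest_metadata()]).
#' @export
simulate_nests <- function(config) {
  n <- config$n_birds
  n_tr <- n %/% 2
  treatment <- sample(rep(c("control", "trimmed"), c(n - n_tr, n_tr)))
  age <- character(n)
  for (grp in c("control", "trimmed")) {
    idx <- which(treatment == grp)
    frac_sy <- if (grp == "control") 2 / 8 else 4 / 8
    n_sy <- round(length(idx) * frac_sy)
    age[idx] <- sample(rep(c("SY", "ASY"),
                           c(n_sy, length(idx) - n_sy)))
  }
  clutch <- ifelse(treatment == "control",
                   sample(5:6, n, replace = TRUE),
                   sample(4:5, n, replace = TRUE))
  brood0 <- pmax(clutch - rbinom(n, clutch, 0.08), 2L)
  hatch <- config$start_date + sample(0:config$hatch_spread, n, replace = TRUE)
  nests <- tibble::tibble(
    nest_id = sprintf("N%02d", seq_len(n)),
    bird_id = sprintf("F%02d", seq_len(n)),
    site = sample(c("lagoon", "nature_area"), n, replace = TRUE),
    treatment = treatment,
    maternal_age = age,
    hatch_date = hatch,
    clutch_size = as.integer(clutch)
  )
  for (d in 0:12) {
    # broods occasionally lose a chick mid-way, never below 2
    nests[[paste0("brood_d", d)]] <- as.integer(pmax(
      brood0 - rbinom(n, 1, 0.02 * d), 2L))
  }
  nests
}

#' Reader coverage schedule
#'
#' Three readers cycle among nests so each nest is covered for
#' approximately 24 h once per provisioning stage. Each window starts at
#' 12:00 on a uniformly chosen nestling day within the stage and runs for
#' `coverage_hours`.
#'
#' @param nests Nest metadata tibble.
#' @param config A [sim_config()].
#' @return Tibble `bird_id`, `stage`, `window_start`, `window_end`.
#' @export
reader_schedule <- function(nests, config) {
  rows <- list()
  for (i in seq_len(nrow(nests))) {
    for (stg in names(config$stages)) {
      rng <- config$stages[[stg]]
      day <- sample(seq(rng[1], min(rng[2], config$days - 1)), 1)
      ws <- as.POSIXct(paste(nests$hatch_date[i] + day, "12:00:00"),
                       tz = ST_TZ)
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = nests$bird_id[i], stage = stg,
        window_start = ws,
        window_end = ws + 3600 * config$coverage_hours
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Visits and latent heat for one bird on one calendar date.
# ta_by_hour: numeric[24], that date's hourly ambient temperatures.
simulate_bird_day <- function(bird, date, ta_by_hour, brood, config) {
  active <- 5:20
  ta_act <- ta_by_hour[active + 1]
  pace <- if (bird$pacing) {
    1 - config$pacing_slope * pmax(ta_act - config$pacing_threshold, 0)
  } else {
    rep(1, length(active))
  }
  # hour-to-hour workload variation independent of the weather (prey
  # availability, chick begging): keeps feeding rate identifiable
  # alongside the Ta terms in the downstream models
  pace <- pmax(pace + rnorm(length(active), 0, config$pacing_noise_sd),
               config$pacing_floor)
  lambda <- config$base_visit_rate * brood * pace
  n_vis <- rpois(length(active), lambda)
  if (sum(n_vis) == 0) {
    return(tibble::tibble(start = as.POSIXct(character(), tz = ST_TZ),
                          end = start, duration = numeric(),
                          h_arr = numeric(), exc = numeric(),
                          ta = numeric(), tau_vis = numeric()))
  }
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = ST_TZ)
  # reader clocks resolve to 1 s
  start_s <- sort(unique(floor(unlist(mapply(
    function(h, n) if (n > 0) 3600 * h + runif(n, 0, 3600) else numeric(0),
    active, n_vis, SIMPLIFY = FALSE
  )))))
  n <- length(start_s)
  resting <- runif(n) < config$resting_prob
  dur <- floor(ifelse(resting,
                      runif(n, config$resting_duration_range[1],
                            config$resting_duration_range[2]),
                      rexp(n, 1 / config$visit_mean_duration)))
  # visits may not overlap: truncate to leave at least the read delay + 1 s
  if (n > 1) {
    dur[-n] <- pmin(dur[-n], diff(start_s) - (config$read_delay + 1))
  }
  dur <- pmax(dur, 0)
  ta_vis <- ta_by_hour[floor(start_s / 3600) + 1]
  s <- config$heat_pulse_sdlog
  q <- config$heat_increment *
    (1 + config$heat_increment_slope * pmax(ta_vis - config$heat_knee, 0)) *
    exp(rnorm(n, -s^2 / 2, s))
  # heat decays slowly between visits (flight cooling offset by exercise
  # heat production), moderately during an ordinary sit, and fast once
  # the bird commits to a long resting/brooding bout (posture change)
  tau_vis <- ifelse(dur >= config$resting_duration_range[1],
                    bird$tau_rest, config$sit_cooling_tau)
  h_arr <- numeric(n)
  h_prev <- 0
  end_prev <- start_s[1]
  for (i in seq_len(n)) {
    h_arr[i] <- h_prev * exp(-max(start_s[i] - end_prev, 0) / bird$tau) + q[i]
    h_prev <- h_arr[i] * exp(-dur[i] / tau_vis[i])
    end_prev <- start_s[i] + dur[i]
  }
  # facultative heat storage: under load, birds let Tb rise above
  # normothermia rather than shedding the heat immediately
  exc_p <- plogis(config$excursion_prob_intercept +
                    config$excursion_prob_slope * h_arr +
                    config$excursion_ta_slope *
                      pmin(pmax(ta_vis - config$excursion_ta_knee, 0),
                           config$excursion_ta_cap))
  # stored load scales with how poorly the bird dissipates and varies
  # from bout to bout (mean-preserving lognormal); a bird that commits to
  # a long resting/brooding sit dumps its load instead of storing it
  s_amp <- config$excursion_amp_sdlog
  exc <- (runif(n) < exc_p) * config$excursion_amp *
    (bird$tau / config$cooling_tau)^config$excursion_amp_power *
    exp(rnorm(n, -s_amp^2 / 2, s_amp))
  tibble::tibble(
    start = day0 + start_s, end = day0 + start_s + dur, duration = dur,
    h_arr = h_arr, exc = exc, ta = ta_vis, tau_vis = tau_vis
  )
}

# Reads emitted for one bird's visits restricted to its coverage windows.
emit_reads_bird <- function(bird, visits, windows, config) {
  if (nrow(visits) == 0) {
    return(tibble::tibble(timestamp = as.POSIXct(character(), tz = ST_TZ),
                          tb = numeric(), latent_tb = numeric(),
                          excursion = logical()))
  }
  offs <- lapply(seq_len(nrow(visits)), function(i) {
    seq(0, visits$duration[i], by = config$read_delay)
  })
  nper <- lengths(offs)
  idx <- rep(seq_len(nrow(visits)), nper)
  off <- unlist(offs)
  t_read <- visits$start[idx] + off
  tn <- as.numeric(t_read)
  covered <- rep(FALSE, length(tn))
  for (j in seq_len(nrow(windows))) {
    covered <- covered |
      (tn >= as.numeric(windows$window_start[j]) &
         tn < as.numeric(windows$window_end[j]))
  }
  idx <- idx[covered]; off <- off[covered]; t_read <- t_read[covered]
  # a stored-heat excursion persists in proportion to how poorly the
  # bird dissipates: untrimmed birds stay hyperthermic for most of a
  # sit, trimmed birds shed the stored load within a couple of reads
  persist <- config$excursion_persist_frac * bird$tau *
    (bird$tau / config$cooling_tau)
  # committing to a long sit starts with a rapid postural heat dump:
  # only a fraction of the arriving load is expressed during the bout
  resting_vis <- visits$duration >= config$resting_duration_range[1]
  h_eff <- visits$h_arr * ifelse(resting_vis, config$rest_heat_dump, 1)
  latent <- bird$t_mod +
    config$ta_coupling * (visits$ta[idx] - 20) +
    h_eff[idx] * exp(-off / visits$tau_vis[idx]) +
    visits$exc[idx] * exp(-off / persist)
  if (bird$treatment == "trimmed") {
    # compensatory heat production engages while active/exposed; inside
    # the sheltered cavity on a long sit the bird is buffered from it
    active_read <- visits$duration[idx] < config$resting_duration_range[1]
    latent <- latent + active_read * pmin(
      config$cold_comp_slope * pmax(config$cold_comp_knee - visits$ta[idx], 0),
      config$cold_comp_cap)
  }
  # rest-phase heterothermy: during long sits Tb is either held tightly
  # at the modal value or allowed to wander (mostly downward)
  resting_read <- visits$duration[idx] >= config$resting_duration_range[1]
  wander_draw <- runif(length(latent)) >= config$rest_settle_prob
  wander <- resting_read & wander_draw
  latent[wander] <- latent[wander] -
    abs(rnorm(sum(wander), abs(config$rest_wander_mean),
              config$rest_wander_sd))
  # regulated ceiling / floor: extreme loads are defended, not expressed
  latent <- pmin(pmax(latent, 35), 46.5)
  tb <- round(latent + rnorm(length(latent), 0, config$obs_noise_sd), 1)
  tb <- pmin(pmax(tb, 30.1), 49.9)
  out <- tibble::tibble(timestamp = t_read, tb = tb, latent_tb = latent,
                        excursion = visits$exc[idx] > 0)
  out <- out[order(out$timestamp), ]
  # the reader enforces the delay interval globally: a tag is not logged
  # again within read_delay seconds of its previous detection
  tn <- as.numeric(out$timestamp)
  keep <- logical(length(tn))
  last <- -Inf
  for (i in seq_along(tn)) {
    if (tn[i] - last >= config$read_delay) {
      keep[i] <- TRUE
      last <- tn[i]
    }
  }
  out[keep, ]
}

#' Simulate a complete field campaign
#'
#' Generates weather, nests, reader schedule, per-bird visit behaviour and
#' latent Tb dynamics, and the emitted PIT-read log, together with the
#' ground truth needed by validation tests. Fully deterministic given
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @param n_aberrant Number of aberrant bird-days to inject (default 0);
#'   each shifts one covered bird-day's 05:00--13:00 reads by
#'   `aberrant_delta`.
#' @param aberrant_delta Injected morning shift, deg C (default -2).
#' @return List with `reads` (bird_id, timestamp, tb), `weather`, `nests`,
#'   `schedule`, `truth` (list: `birds` tibble with per-bird `t_mod`,
#'   `tau`, `pacing`; `reads` tibble with per-read `latent_tb` and
#'   `excursion`; `visits`, the true visit process before reader
#'   censoring; `aberrant` tibble), `config`, `seed`.
#' @export
simulate_campaign <- function(config = sim_config(), seed = 1,
                              n_aberrant = 0, aberrant_delta = -2) {
  set.seed(seed)
  weather <- simulate_weather(config)
  nests <- simulate_nests(config)
  schedule <- reader_schedule(nests, config)
  ta_lookup <- matrix(weather$ta, nrow = 24)
  colnames(ta_lookup) <- as.character(
    unique(date_of(weather$hour_start)))
  birds <- tibble::tibble(
    bird_id = nests$bird_id,
    treatment = nests$treatment,
    t_mod = rnorm(nrow(nests), config$tmod_mean, config$tmod_sd),
    tau = ifelse(nests$treatment == "trimmed",
                 config$cooling_tau * config$dissipation_multiplier,
                 config$cooling_tau),
    # trimming exposes the brood patch to airflow, so the dissipation
    # advantage applies in flight; cooling while sitting is similar
    tau_rest = config$resting_cooling_tau,
    pacing = nests$treatment == "control"
  )
  all_reads <- list()
  truth_reads <- list()
  truth_visits <- list()
  for (i in seq_len(nrow(birds))) {
    bird <- as.list(birds[i, ])
    win <- schedule[schedule$bird_id == bird$bird_id, ]
    dates <- sort(unique(c(date_of(win$window_start),
                           date_of(win$window_end - 1))))
    day_visits <- lapply(dates, function(d) {
      ta_col <- ta_lookup[, as.character(d)]
      nd <- as.integer(d - nests$hatch_date[i])
      brood <- brood_size(nests, bird$bird_id, max(nd, 0L))
      simulate_bird_day(bird, d, ta_col, brood, config)
    })
    visits <- dplyr::bind_rows(day_visits)
    reads <- emit_reads_bird(bird, visits, win, config)
    all_reads[[i]] <- tibble::tibble(
      bird_id = bird$bird_id, timestamp = reads$timestamp, tb = reads$tb
    )
    truth_reads[[i]] <- tibble::tibble(
      bird_id = bird$bird_id, timestamp = reads$timestamp,
      latent_tb = reads$latent_tb, excursion = reads$excursion
    )
    truth_visits[[i]] <- tibble::tibble(
      bird_id = bird$bird_id, start = visits$start,
      duration = visits$duration, ta = visits$ta
    )
  }
  reads <- dplyr::arrange(dplyr::bind_rows(all_reads),
                          .data$bird_id, .data$timestamp)
  truth <- list(
    birds = birds,
    reads = dplyr::bind_rows(truth_reads),
    visits = dplyr::bind_rows(truth_visits),
    aberrant = tibble::tibble(bird_id = character(), day = as.Date(character()),
                              delta = numeric())
  )
  if (n_aberrant > 0) {
    # the emulated artefact is a *monitored* morning reading low, so only
    # bird-days with substantial morning coverage are candidates
    hr <- hour_of(reads$timestamp)
    mo <- tibble::tibble(
      bird_id = reads$bird_id[hr >= 5 & hr < 13],
      day = date_of(reads$timestamp[hr >= 5 & hr < 13]),
      hour = hr[hr >= 5 & hr < 13])
    cover <- dplyr::summarise(
      dplyr::group_by(mo, .data$bird_id, .data$day),
      n_hours = dplyr::n_distinct(.data$hour),
      n_reads = dplyr::n(), .groups = "drop")
    morning <- cover[cover$n_hours >= 5 & cover$n_reads >= 20,
                     c("bird_id", "day")]
    pick <- morning[sample(nrow(morning), min(n_aberrant, nrow(morning))), ]
    for (j in seq_len(nrow(pick))) {
      inj <- inject_aberrant_day(reads, pick$bird_id[j], pick$day[j],
                                 delta = aberrant_delta)
      reads <- inj$reads
      truth$aberrant <- dplyr::bind_rows(truth$aberrant, inj$entry)
    }
  }
  list(reads = reads, weather = weather, nests = nests, schedule = schedule,
       truth = truth, config = config, seed = seed)
}

#' Inject an aberrant bird-day into a read log
#'
#' Shifts one bird's reads between 05:00 and 13:00 on one day by `delta`
#' deg C, mimicking the sensor/placement artefact that the aberrant-day
#' screen is designed to catch.
#'
#' @param reads Read tibble.
#' @param bird_id,day Target bird and calendar day.
#' @param delta Shift in deg C (default -2).
#' @param window Morning window, `c(first_hour, one_past_last_hour)`.
#' @return List with modified `reads` and a one-row `entry` tibble for the
#'   ground-truth ledger.
#' @export
inject_aberrant_day <- function(reads, bird_id, day, delta = -2,
                                window = c(5L, 13L)) {
  hr <- hour_of(reads$timestamp)
  hit <- reads$bird_id == bird_id &
    date_of(reads$timestamp) == as.Date(day) &
    hr >= window[1] & hr < window[2]
  reads$tb[hit] <- reads$tb[hit] + delta
  list(
    reads = reads,
    entry = tibble::tibble(bird_id = bird_id, day = as.Date(day),
                           delta = delta, n_reads_shifted = sum(hit))
  )
}

#' True visit intensity of the simulator
#'
#' The expected visit rate (visits per hour) for a bird of a given
#' treatment at ambient temperature `ta` with `brood` chicks -- the
#' ground-truth rate of the thinned-Poisson visit process, for
#' rate-recovery checks.
#'
#' @param ta Ambient temperature, deg C.
#' @param treatment `"control"` or `"trimmed"`.
#' @param brood Brood size.
#' @param config A [sim_config()].
#' @return Expected visits per hour.
#' @export
true_visit_rate <- function(ta, treatment, brood, config = sim_config()) {
  pace <- ifelse(
    treatment == "control",
    pmax(1 - config$pacing_slope * pmax(ta - config$pacing_threshold, 0),
         config$pacing_floor),
    1)
  config$base_visit_rate * brood * pace
}
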