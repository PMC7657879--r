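#' Modal resting body temperature
#'
#' The mode of a bird's resting body temperatures after binning to the
#' sensor's reporting resolution (0.1 deg C by default). Ties between bins
#' are broken toward the lowest candidate: a lower mode gives a lower
#' hyperthermia threshold and therefore flags *more* observations as
#' hyperthermic, which is the conservative direction for the questions
#' this pipeline asks.
#'
#' @param tbs Numeric vector of resting body temperatures (deg C).
#' @param bin_width Bin width in deg C, default 0.1.
#' @return The modal temperature (centre of the winning bin), deg C.
#' @export
modal_tb <- function(tbs, bin_width = 0.1) {
  tbs <- tbs[!is.na(tbs)]
  if (length(tbs) < 2) {
    abort("modal_tb: need at least 2 resting observations")
  }
  bins <- round(tbs / bin_width)
  counts <- table(bins)
  winners <- as.numeric(names(counts)[counts == max(counts)])
  min(winners) * bin_width
}

#' Heterothermy index
#'
#' Root-mean-square deviation of body temperature from the modal value,
#' with an n - 1 denominator:
#' \deqn{HI = \sqrt{\sum_i (T_{mod} - T_{b,i})^2 / (n - 1)}}
#' Like a standard deviation, but anchored at the mode rather than the
#' mean, so that regulated departures from normothermia (in either
#' direction) contribute.
#'
#' @param tbs Numeric vector of body temperatures (deg C), n >= 2.
#' @param t_mod Modal body temperature (deg C).
#' @return HI in deg C (non-negative).
#' @export
heterothermy_index <- function(tbs, t_mod) {
  tbs <- tbs[!is.na(tbs)]
  n <- length(tbs)
  if (n < 2) abort("heterothermy_index: need at least 2 observations")
  sqrt(sum((t_mod - tbs)^2) / (n - 1))
}

#' Per-bird thermal profiles
#'
#' Computes, for each bird with at least `min_obs` resting observations,
#' the modal resting Tb, the heterothermy index over those same resting
#' observations, and the individual hyperthermia threshold
#' `t_mod + hi` (the upper bound on Tb during rest).
#'
#' @param resting_obs Tibble from [resting_observations()].
#' @param bin_width Mode bin width, deg C.
#' @param min_obs Minimal resting observations per bird (default 2); birds
#'   below it are dropped with a warning.
#' @return Tibble `bird_id`, `t_mod`, `hi`, `threshold`, `n_resting_obs`.
#' @export
thermal_profiles <- function(resting_obs, bin_width = 0.1, min_obs = 2) {
  counts <- table(resting_obs$bird_id)
  low <- names(counts)[counts < max(2, min_obs)]
  if (length(low) > 0) {
    warn(sprintf("thermal_profiles: dropping %d bird(s) with < %d resting obs",
                 length(low), max(2, min_obs)))
  }
  keep <- setdiff(names(counts), low)
  rows <- lapply(keep, function(b) {
    tbs <- resting_obs$tb[resting_obs$bird_id == b]
    tm <- modal_tb(tbs, bin_width)
    hi <- heterothermy_index(tbs, tm)
    tibble::tibble(bird_id = b, t_mod = tm, hi = hi,
                   threshold = tm + hi, n_resting_obs = length(tbs))
  })
  dplyr::bind_rows(rows)
}

#' Classify observations as normothermic or hyperthermic
#'
#' An observation is hyperthermic when body temperature *surpasses* the
#' bird's threshold (modal Tb + HI): the comparison is strictly greater,
#' so Tb exactly at the threshold is normothermic.
#'
#' @param tb Numeric vector of body temperatures.
#' @param profile Either a one-row thermal profile (with `$threshold`) or
#'   a numeric threshold.
#' @return Logical vector: `TRUE` = hyperthermic.
#' @export
classify_observation <- function(tb, profile) {
  threshold <- if (is.numeric(profile)) profile else profile$threshold
  if (length(threshold) != 1 || !is.finite(threshold)) {
    abort("classify_observation: need a single finite threshold")
  }
  tb > threshold
}

#' Build the bird-hour analysis table
#'
#' Aggregates every read (not only resting ones) into one row per bird and
#' clock hour: total observations, hyperthermic observations (strictly
#' above the bird's threshold), their proportion, and the plain mean Tb of
#' the hour, joined with ambient temperature, per-chick feeding rate and
#' the bird-level covariates. Hours with no reads produce no row.
#'
#' @param reads Read tibble.
#' @param profiles Thermal profile tibble from [thermal_profiles()]; birds
#'   without a profile are dropped.
#' @param weather Hourly weather tibble; hours without a matching weather
#'   record get `ta = NA`.
#' @param nests Nest metadata tibble.
#' @param feeding Feeding-rate tibble (`bird_id`, `hour_start`,
#'   `feeding_rate`), e.g. from [hourly_feeding_rate()]; bird-hours absent
#'   from it get rate 0 (reads but no visit start in the hour).
#' @return Bird-hour tibble with the columns documented in
#'   [write_bird_hours()].
#' @export
aggregate_bird_hours <- function(reads, profiles, weather, nests, feeding) {
  df <- dplyr::inner_join(
    reads, profiles[, c("bird_id", "threshold")], by = "bird_id"
  )
  df$hour_start <- floor_hour(df$timestamp)
  df$hyper <- df$tb > df$threshold
  hours <- dplyr::summarise(
    dplyr::group_by(df, .data$bird_id, .data$hour_start),
    n_obs = dplyr::n(),
    n_hyper = sum(.data$hyper),
    mean_tb = mean(.data$tb),
    hi_threshold = .data$threshold[1],
    .groups = "drop"
  )
  hours$n_obs <- as.integer(hours$n_obs)
  hours$n_hyper <- as.integer(hours$n_hyper)
  hours$any_hyper <- hours$n_hyper > 0L
  hours$prop_hyper <- hours$n_hyper / hours$n_obs
  hours$hour_of_day <- as.integer(hour_of(hours$hour_start))
  hours <- dplyr::left_join(hours, weather, by = "hour_start")
  if (!"ta" %in% names(hours)) hours$ta <- NA_real_
  meta <- nests[, c("bird_id", "treatment", "maternal_age", "hatch_date")]
  hours <- dplyr::inner_join(hours, meta, by = "bird_id")
  hours$nestling_age <- as.integer(date_of(hours$hour_start) - hours$hatch_date)
  hours$hatch_date <- NULL
  fr <- feeding[, c("bird_id", "hour_start", "n_visits", "brood_size",
                    "feeding_rate")]
  hours <- dplyr::left_join(hours, fr, by = c("bird_id", "hour_start"))
  hours$feeding_rate[is.na(hours$feeding_rate)] <- 0
  miss_bs <- is.na(hours$brood_size)
  if (any(miss_bs)) {
    day <- pmax(as.integer(hours$nestling_age[miss_bs]), 0L)
    hours$brood_size[miss_bs] <- mapply(
      function(b, d) tryCatch(brood_size(nests, b, d),
                              error = function(e) NA_integer_),
      hours$bird_id[miss_bs], day
    )
  }
  hours$n_visits <- NULL
  dplyr::arrange(hours[, BIRD_HOUR_COLS], .data$bird_id, .data$hour_start)
}
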