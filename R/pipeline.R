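#' Analyse a campaign held in memory
#'
#' Runs every analysis stage on in-memory inputs: the aberrant-day
#' screen, visit segmentation and resting-bout flagging, per-bird thermal
#' profiles (modal resting Tb, HI, hyperthermia threshold), hourly
#' feeding rates, the bird-hour table, the inclusion filters, and
#' (optionally) the inferential models.
#'
#' Resting observations used for the thermal profiles are restricted to
#' the same window as the analyses proper: daytime hours (05:00--21:00)
#' and nestling days `age_range`.
#'
#' @param reads Read tibble (e.g. [read_pit_log()] output).
#' @param weather Weather tibble.
#' @param nests Nest metadata tibble.
#' @param gap_threshold Visit segmentation gap, s.
#' @param resting_min_duration Resting-bout cut-off, s.
#' @param age_range,hour_range,ta_max Passed to [apply_inclusion()].
#' @param aberrant_delta Aberrant-day screening threshold, deg C.
#' @param models Character subset of `c("lmm", "ttest", "hurdle")`
#'   naming which model groups to fit (`NULL` fits none).
#' @param tweedie_power Variance power for [fit_prop_hyper()].
#' @return A list of stage outputs: `aberrant`, `visits`, `profiles`,
#'   `bird_hours` (unfiltered), `rows` (filtered), `filter_report`,
#'   `models` (list), `stage_counts`.
#' @export
analyze_campaign <- function(reads, weather, nests,
                             gap_threshold = 120,
                             resting_min_duration = 300,
                             age_range = c(3L, 14L),
                             hour_range = c(5L, 20L),
                             ta_max = 30.9,
                             aberrant_delta = 1.25,
                             models = c("lmm", "ttest", "hurdle"),
                             tweedie_power = 1.5) {
  counts <- list(reads_in = nrow(reads))
  flagged <- detect_aberrant_days(reads, delta = aberrant_delta)
  reads <- remove_aberrant_days(reads, flagged)
  counts$reads_after_aberrant_screen <- nrow(reads)

  visits <- segment_visits(reads, gap_threshold, resting_min_duration)
  counts$visits <- nrow(visits)
  counts$resting_visits <- sum(visits$is_resting)

  rest_obs <- resting_observations(reads, visits)
  hatch <- setNames(nests$hatch_date, nests$bird_id)
  in_window <- function(tb_rows) {
    hr <- hour_of(tb_rows$timestamp)
    age <- as.integer(date_of(tb_rows$timestamp) -
                        hatch[tb_rows$bird_id])
    tb_rows[hr >= hour_range[1] & hr <= hour_range[2] &
              age >= age_range[1] & age <= age_range[2], , drop = FALSE]
  }
  rest_obs <- in_window(rest_obs)
  counts$resting_observations <- nrow(rest_obs)
  profiles <- thermal_profiles(rest_obs)

  feeding <- dplyr::bind_rows(lapply(
    unique(visits$bird_id),
    function(b) hourly_feeding_rate(visits[visits$bird_id == b, ], nests)
  ))
  bird_hours <- aggregate_bird_hours(reads, profiles, weather, nests, feeding)
  counts$bird_hours <- nrow(bird_hours)
  filt <- apply_inclusion(bird_hours, age_range, hour_range, ta_max)
  rows <- filt$rows
  counts$bird_hours_filtered <- nrow(rows)

  fits <- list()
  if ("lmm" %in% models) {
    for (d in 1:3) {
      fits[[sprintf("tb_lmm_ta%d", d)]] <- fit_lmm_tb(rows, ta_degree = d)
    }
    fits$tb_lmm_reml <- fit_lmm_tb(rows, ta_degree = 3, REML = TRUE)
    fits$lr_1_vs_2 <- lr_test(fits$tb_lmm_ta1, fits$tb_lmm_ta2)
    fits$lr_2_vs_3 <- lr_test(fits$tb_lmm_ta2, fits$tb_lmm_ta3)
    fits$aic <- tibble::tibble(
      model = sprintf("tb_lmm_ta%d", 1:3),
      log_likelihood = vapply(1:3, function(d)
        fits[[sprintf("tb_lmm_ta%d", d)]]$log_likelihood, numeric(1)),
      n_parameters = vapply(1:3, function(d)
        fits[[sprintf("tb_lmm_ta%d", d)]]$n_parameters, integer(1)),
      aic = vapply(1:3, function(d)
        model_aic(fits[[sprintf("tb_lmm_ta%d", d)]]), numeric(1))
    )
  }
  if ("ttest" %in% models) {
    pro <- dplyr::inner_join(profiles,
                             nests[, c("bird_id", "treatment")], by = "bird_id")
    fits$threshold_ttest <- t_test_thresholds(
      pro$threshold[pro$treatment == "control"],
      pro$threshold[pro$treatment == "trimmed"]
    )
  }
  if ("hurdle" %in% models) {
    fits$any_hyper <- tryCatch(fit_any_hyper(rows), error = function(e) e)
    fits$prop_hyper <- tryCatch(fit_prop_hyper(rows, power = tweedie_power),
                                error = function(e) e)
  }

  list(
    aberrant = flagged, visits = visits, profiles = profiles,
    bird_hours = bird_hours, rows = rows, filter_report = filt$report,
    models = fits, stage_counts = counts
  )
}

#' Run the full simulate-and-analyse pipeline against files on disk
#'
#' Either simulates a campaign (writing the three input files plus a
#' ground-truth sidecar under `out_dir/inputs/`) or takes existing input
#' paths, then reads the inputs back through the package's readers, runs
#' [analyze_campaign()], and writes the output tables and a reproducible
#' run manifest under `out_dir`. Re-running with the same config and seed
#' reproduces identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()] (also carries analysis defaults).
#' @param seed Integer seed for the simulation.
#' @param inputs Optional named list with paths `pit_log`, `weather`,
#'   `nests`; when given, nothing is simulated.
#' @param n_aberrant Aberrant bird-days to inject when simulating.
#' @param ... Passed to [analyze_campaign()].
#' @return The [analyze_campaign()] result list, invisibly, with
#'   `manifest` attached.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1,
                         inputs = NULL, n_aberrant = 0, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputs)) {
    camp <- simulate_campaign(config, seed, n_aberrant = n_aberrant)
    in_dir <- file.path(out_dir, "inputs")
    dir.create(in_dir, showWarnings = FALSE)
    inputs <- list(
      pit_log = file.path(in_dir, "pit_reads.csv"),
      weather = file.path(in_dir, "weather.csv"),
      nests = file.path(in_dir, "nests.csv")
    )
    write_pit_log(camp$reads, inputs$pit_log)
    write_weather(camp$weather, inputs$weather)
    write_nest_metadata(camp$nests, inputs$nests)
    truth_out <- list(
      birds = camp$truth$birds,
      aberrant = dplyr::mutate(camp$truth$aberrant,
                               day = as.character(.data$day))
    )
    jsonlite::write_json(truth_out, file.path(in_dir, "ground_truth.json"),
                         dataframe = "rows", digits = NA)
  }
  for (nm in c("pit_log", "weather", "nests")) {
    if (!file.exists(inputs[[nm]])) {
      abort(sprintf("run_pipeline: %s file not found: '%s'", nm, inputs[[nm]]))
    }
  }
  reads <- read_pit_log(inputs$pit_log)
  weather <- read_weather(inputs$weather)
  nests <- read_nest_metadata(inputs$nests)

  res <- analyze_campaign(reads, weather, nests, ...)

  write_bird_hours(res$rows, file.path(out_dir, "bird_hours.csv"))
  readr::write_csv(res$profiles, file.path(out_dir, "thermal_profiles.csv"))
  readr::write_csv(res$filter_report, file.path(out_dir, "filter_report.csv"))
  if (nrow(res$aberrant) > 0) {
    readr::write_csv(res$aberrant, file.path(out_dir, "aberrant_days.csv"))
  }
  for (nm in c("tb_lmm_reml", "any_hyper", "prop_hyper")) {
    f <- res$models[[nm]]
    if (inherits(f, "st_model_fit")) {
      readr::write_csv(f$coefficients,
                       file.path(out_dir, paste0("model_", nm, ".csv")))
    }
  }
  if (!is.null(res$models$aic)) {
    sel <- res$models$aic
    sel$lr_statistic <- c(NA, res$models$lr_1_vs_2$statistic,
                          res$models$lr_2_vs_3$statistic)
    sel$lr_p <- c(NA, res$models$lr_1_vs_2$p_value,
                  res$models$lr_2_vs_3$p_value)
    readr::write_csv(sel, file.path(out_dir, "model_selection.csv"))
  }
  if (!is.null(res$models$threshold_ttest)) {
    readr::write_csv(res$models$threshold_ttest,
                     file.path(out_dir, "threshold_ttest.csv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("swallowtherm")),
    seed = seed,
    config_hash = rlang::hash(config),
    input_digests = lapply(inputs, function(p)
      rlang::hash(readChar(p, file.size(p)))),
    stage_counts = res$stage_counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Human-readable campaign summary
#'
#' Group means and pooled hyperthermia fractions: the pooled percentage
#' is computed exactly as total hyperthermic observations over total
#' observations within each treatment, plus the headline model
#' coefficients when present.
#'
#' @param res Result list from [analyze_campaign()] / [run_pipeline()].
#' @return A list of class `st_summary` with `pooled` (per-treatment
#'   totals and percentages), `mean_tb`, `thresholds`, and `headline`
#'   coefficients; printed compactly.
#' @export
report_summary <- function(res) {
  rows <- res$rows
  pooled <- dplyr::summarise(
    dplyr::group_by(rows, .data$treatment),
    n_obs = sum(.data$n_obs),
    n_hyper = sum(.data$n_hyper),
    pct_hyper = 100 * sum(.data$n_hyper) / sum(.data$n_obs),
    .groups = "drop"
  )
  mean_tb <- dplyr::summarise(
    dplyr::group_by(rows, .data$treatment),
    sem = sd(.data$mean_tb) / sqrt(dplyr::n()),
    mean_tb = mean(.data$mean_tb),
    .groups = "drop"
  )[, c("treatment", "mean_tb", "sem")]
  thresholds <- NULL
  if (!is.null(res$profiles) && nrow(res$profiles) > 0) {
    pro <- dplyr::inner_join(
      res$profiles,
      dplyr::distinct(rows[, c("bird_id", "treatment")]), by = "bird_id")
    thresholds <- dplyr::summarise(
      dplyr::group_by(pro, .data$treatment),
      mean_t_mod = mean(.data$t_mod),
      mean_hi = mean(.data$hi),
      mean_threshold = mean(.data$threshold),
      .groups = "drop"
    )
  }
  headline <- list()
  coef_of <- function(fit, pattern) {
    if (!inherits(fit, "st_model_fit")) return(NULL)
    hit <- grep(pattern, fit$coefficients$term)
    if (length(hit) == 0) return(NULL)
    fit$coefficients[hit, ]
  }
  headline$treatment_x_ta2 <- coef_of(res$models$tb_lmm_reml,
                                      "treatment.*poly.*2$|2$")
  headline$prop_treatment <- coef_of(res$models$prop_hyper,
                                     "^treatmenttrimmed$")
  structure(list(pooled = pooled, mean_tb = mean_tb,
                 thresholds = thresholds, headline = headline),
            class = "st_summary")
}

#' @export
print.st_summary <- function(x, ...) {
  cat("Pooled hyperthermic observations by treatment:\n")
  print(x$pooled)
  cat("\nMean of hourly mean Tb by treatment (deg C):\n")
  print(x$mean_tb)
  if (!is.null(x$thresholds)) {
    cat("\nMean modal Tb, HI and hyperthermia threshold by treatment:\n")
    print(x$thresholds)
  }
  if (!is.null(x$headline$prop_treatment)) {
    cat("\nTreatment effect, positive-part (Tweedie) hyperthermia model:\n")
    print(x$headline$prop_treatment)
  }
  invisible(x)
}
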