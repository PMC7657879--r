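#' Read a PIT-tag reader log
#'
#' Reads a delimited log of thermal PIT-tag detections, one row per read:
#' `bird_id`, `timestamp` (ISO-8601 local time, 1 s resolution) and `tb`
#' (subcutaneous body temperature, deg C). Rows that cannot be parsed, or
#' whose temperature is non-finite or outside the physiological range
#' 30--50 deg C, are rejected: they are counted, reported with their line
#' numbers, and returned in the `"rejects"` attribute rather than silently
#' dropped. Field loggers glitch; the read fails only when more than
#' `max_reject_frac` of the data rows reject, otherwise it warns.
#'
#' @param path Path to a CSV file with header `bird_id,timestamp,tb`.
#' @param max_reject_frac Maximal tolerated fraction of rejected rows
#'   (default 0.1) before the read is treated as a format error.
#' @return A tibble with columns `bird_id` (character), `timestamp`
#'   (POSIXct) and `tb` (double), sorted by (`bird_id`, `timestamp`).
#'   Attribute `"rejects"` holds a tibble of rejected rows (`line`,
#'   `reason`).
#' @export
read_pit_log <- function(path, max_reject_frac = 0.1) {
  raw <- read_text_csv(path, c("bird_id", "timestamp", "tb"))
  ts <- parse_ts(raw$timestamp)
  tb <- suppressWarnings(as.numeric(raw$tb))
  bad_ts <- is.na(ts)
  bad_tb <- is.na(tb) | !is.finite(tb) | tb < 30 | tb > 50
  reason <- dplyr::case_when(
    bad_ts & bad_tb ~ "unparseable timestamp and tb",
    bad_ts ~ "unparseable timestamp",
    bad_tb ~ "non-numeric or out-of-range tb",
    TRUE ~ NA_character_
  )
  bad <- bad_ts | bad_tb
  rejects <- tibble::tibble(line = which(bad) + 1L, reason = reason[bad])
  if (nrow(raw) > 0 && nrow(rejects) / nrow(raw) > max_reject_frac) {
    abort(sprintf(
      "read_pit_log: %d of %d rows rejected (> %.0f%%) in '%s'",
      nrow(rejects), nrow(raw), 100 * max_reject_frac, path
    ))
  }
  if (nrow(rejects) > 0) {
    warn(sprintf("read_pit_log: %d malformed row(s) rejected in '%s'",
                 nrow(rejects), path))
  }
  out <- tibble::tibble(
    bird_id = raw$bird_id[!bad],
    timestamp = ts[!bad],
    tb = tb[!bad]
  )
  out <- dplyr::arrange(out, .data$bird_id, .data$timestamp)
  attr(out, "rejects") <- rejects
  out
}

#' Write a PIT-tag reader log
#'
#' Inverse of [read_pit_log()]; timestamps are written as ISO-8601 local
#' time so that a read/write/read cycle is lossless.
#'
#' @param reads Tibble with `bird_id`, `timestamp`, `tb`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pit_log <- function(reads, path) {
  out <- tibble::tibble(
    bird_id = reads$bird_id,
    timestamp = format_ts(reads$timestamp),
    tb = format_num(reads$tb)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an hourly weather series
#'
#' One row per clock hour: `hour_start` (ISO-8601) and `ta` (ambient
#' temperature, deg C). Gaps are allowed; duplicated hours are a data
#' error, as is an empty file.
#'
#' @param path CSV path with header `hour_start,ta`.
#' @return Tibble with POSIXct `hour_start` and double `ta`, sorted by hour.
#' @export
read_weather <- function(path) {
  raw <- read_text_csv(path, c("hour_start", "ta"))
  if (nrow(raw) == 0) abort(sprintf("read_weather: '%s' has no data rows", path))
  hour_start <- parse_ts(raw$hour_start)
  ta <- suppressWarnings(as.numeric(raw$ta))
  if (anyNA(hour_start)) abort("read_weather: unparseable hour_start value(s)")
  if (anyNA(ta) || any(!is.finite(ta))) {
    abort("read_weather: non-numeric or non-finite ta value(s)")
  }
  if (anyDuplicated(hour_start) > 0) {
    dup <- format_ts(hour_start[duplicated(hour_start)][1])
    abort(sprintf("read_weather: duplicated hour %s", dup))
  }
  dplyr::arrange(tibble::tibble(hour_start = hour_start, ta = ta),
                 .data$hour_start)
}

#' @rdname read_weather
#' @param weather Tibble with `hour_start`, `ta`.
#' @export
write_weather <- function(weather, path) {
  out <- tibble::tibble(
    hour_start = format_ts(weather$hour_start),
    ta = format_num(weather$ta)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read nest/bird metadata
#'
#' One row per focal female: `nest_id`, `bird_id`, `site`, `treatment`
#' (`control` or `trimmed`), `maternal_age` (`SY` or `ASY`), `hatch_date`
#' (ISO date, nestling day 0), `clutch_size`, and brood-size columns
#' `brood_d<j>` giving the brood size measured on nestling day `j`.
#' Unknown treatment or age labels are an error.
#'
#' @param path CSV path.
#' @return Tibble, one row per bird.
#' @seealso [brood_size()] for the day-lookup rule.
#' @export
read_nest_metadata <- function(path) {
  req <- c("nest_id", "bird_id", "site", "treatment", "maternal_age",
           "hatch_date", "clutch_size")
  raw <- read_text_csv(path, req)
  if (nrow(raw) == 0) abort(sprintf("read_nest_metadata: '%s' is empty", path))
  bad_tr <- setdiff(unique(raw$treatment), c("control", "trimmed"))
  if (length(bad_tr) > 0) {
    abort(sprintf("read_nest_metadata: unknown treatment label '%s'", bad_tr[1]))
  }
  bad_age <- setdiff(unique(raw$maternal_age), c("SY", "ASY"))
  if (length(bad_age) > 0) {
    abort(sprintf("read_nest_metadata: unknown maternal_age label '%s'",
                  bad_age[1]))
  }
  brood_cols <- grep("^brood_d[0-9]+$", names(raw), value = TRUE)
  out <- dplyr::mutate(
    raw,
    hatch_date = as.Date(.data$hatch_date),
    clutch_size = as.integer(.data$clutch_size),
    dplyr::across(dplyr::all_of(brood_cols), as.integer)
  )
  if (any(out$clutch_size <= 0, na.rm = TRUE)) {
    abort("read_nest_metadata: clutch sizes must be positive")
  }
  tibble::as_tibble(out)
}

#' @rdname read_nest_metadata
#' @param nests Tibble as returned by [read_nest_metadata()].
#' @export
write_nest_metadata <- function(nests, path) {
  out <- dplyr::mutate(nests, hatch_date = as.character(.data$hatch_date))
  readr::write_csv(out, path)
  invisible(path)
}

#' Look up brood size on a nestling day
#'
#' Brood sizes are recorded up to nestling day 12; nests are not visited
#' afterwards, so queries for days 13--14 return the day-12 value. A
#' missing value for a required day is an error.
#'
#' @param nests Nest metadata tibble.
#' @param bird_id Single bird identifier.
#' @param day Nestling day (integer, may exceed 12).
#' @return Integer brood size.
#' @export
brood_size <- function(nests, bird_id, day) {
  row <- nests[nests$bird_id == bird_id, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(sprintf("brood_size: bird '%s' not found (or duplicated)", bird_id))
  }
  day_used <- min(as.integer(day), 12L)
  col <- paste0("brood_d", day_used)
  if (!col %in% names(row) || is.na(row[[col]])) {
    abort(sprintf("brood_size: no brood size recorded for bird '%s' day %d",
                  bird_id, day_used))
  }
  as.integer(row[[col]])
}

# fixed column order of the hour-level analysis table
BIRD_HOUR_COLS <- c(
  "bird_id", "hour_start", "hour_of_day", "nestling_age", "n_obs", "n_hyper",
  "any_hyper", "prop_hyper", "mean_tb", "feeding_rate", "brood_size", "ta",
  "treatment", "maternal_age", "hi_threshold"
)

#' Write / read the bird-hour analysis table
#'
#' The bird-hour table is the analysis unit of the inferential stage: one
#' row per bird x clock hour with at least one tag read. Columns are
#' written in a fixed order and round-trip losslessly.
#'
#' @param rows Bird-hour tibble (see [aggregate_bird_hours()]).
#' @param path CSV path.
#' @return `path` invisibly (write) or the tibble (read).
#' @export
write_bird_hours <- function(rows, path) {
  miss <- setdiff(BIRD_HOUR_COLS, names(rows))
  if (length(miss) > 0) {
    abort(sprintf("write_bird_hours: missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  out <- rows[, BIRD_HOUR_COLS]
  out$hour_start <- format_ts(out$hour_start)
  for (col in c("prop_hyper", "mean_tb", "feeding_rate", "ta", "hi_threshold")) {
    out[[col]] <- format_num(out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_bird_hours
#' @export
read_bird_hours <- function(path) {
  raw <- read_text_csv(path, BIRD_HOUR_COLS)
  tibble::tibble(
    bird_id = raw$bird_id,
    hour_start = parse_ts(raw$hour_start),
    hour_of_day = as.integer(raw$hour_of_day),
    nestling_age = as.integer(raw$nestling_age),
    n_obs = as.integer(raw$n_obs),
    n_hyper = as.integer(raw$n_hyper),
    any_hyper = as.logical(raw$any_hyper),
    prop_hyper = as.numeric(raw$prop_hyper),
    mean_tb = as.numeric(raw$mean_tb),
    feeding_rate = as.numeric(raw$feeding_rate),
    brood_size = as.integer(raw$brood_size),
    ta = as.numeric(raw$ta),
    treatment = raw$treatment,
    maternal_age = raw$maternal_age,
    hi_threshold = as.numeric(raw$hi_threshold)
  )
}

# Read a CSV with every column as character, checking required columns.
read_text_csv <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("input file not found: '%s'", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("'%s': missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  raw
}

# Full-precision numeric text (round-trips doubles exactly via %.17g,
# trimmed to the shortest representation that survives).
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (digits in 1:17) {
      s <- sprintf("%.*g", digits, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
  out
}
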