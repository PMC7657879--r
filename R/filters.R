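#' Apply the standard inclusion rules to the bird-hour table
#'
#' Three conjunctive rules, in any order (they commute):
#' \itemize{
#'   \item nestling age between `age_range[1]` and `age_range[2]` days
#'     (default 3--14), to avoid post-capture behavioural bias;
#'   \item clock hour of day within `hour_range` (default hours starting
#'     05:00 through 20:00, i.e. data spanning 05:00--21:00 -- birds are
#'     inactive overnight and Tb falls from about 20:30);
#'   \item ambient temperature at most `ta_max` deg C (default 30.9; the
#'     boundary value itself is kept). Rows with missing `ta` are dropped
#'     by this rule.
#' }
#'
#' @param rows Bird-hour tibble.
#' @param age_range Integer length-2, inclusive nestling-day range.
#' @param hour_range Integer length-2, inclusive range of `hour_of_day`.
#' @param ta_max Maximal ambient temperature, deg C.
#' @return List with `rows` (the filtered tibble) and `report`, a tibble
#'   with one row per rule: `rule`, `rows_before`, `rows_after`,
#'   `birds_affected`.
#' @export
apply_inclusion <- function(rows, age_range = c(3L, 14L),
                            hour_range = c(5L, 20L), ta_max = 30.9) {
  rules <- list(
    nestling_age = function(d) {
      d$nestling_age >= age_range[1] & d$nestling_age <= age_range[2]
    },
    hour_of_day = function(d) {
      d$hour_of_day >= hour_range[1] & d$hour_of_day <= hour_range[2]
    },
    ta_cap = function(d) !is.na(d$ta) & d$ta <= ta_max
  )
  report <- list()
  for (nm in names(rules)) {
    keep <- rules[[nm]](rows)
    keep[is.na(keep)] <- FALSE
    affected <- length(setdiff(unique(rows$bird_id[!keep]),
                               character(0)))
    report[[nm]] <- tibble::tibble(
      rule = nm,
      rows_before = nrow(rows),
      rows_after = sum(keep),
      birds_affected = affected
    )
    rows <- rows[keep, , drop = FALSE]
  }
  if (nrow(rows) == 0) warn("apply_inclusion: no rows remain after filtering")
  list(rows = rows, report = dplyr::bind_rows(report))
}

#' Screen for aberrant bird-days
#'
#' Flags (bird, day) pairs whose morning body temperature is abnormally
#' low: the morning index on day d is at least `delta` deg C below the
#' mean of the bird's morning indices on all its *other* days. The index
#' is the upper quartile of the early-morning readings (05:00--10:00 by
#' default, when ambient heat loads are still low): it tracks the bird's
#' active normothermic level and is insensitive both to how much of a
#' morning was spent in resting bouts (where Tb is naturally lower and
#' more variable) and to late-morning heat. A sensor or placement
#' artefact shifts the whole morning, index included; days with fewer
#' than `min_reads` readings in the window are neither flagged nor used
#' in the baseline. A bird observed on a single day is never
#' flagged. The screen operationalizes the visual raw-data check used in
#' field studies, where one bird-day roughly 2 deg C low is the kind of
#' sensor/placement artefact that gets removed; the default `delta` of
#' 1.25 deg C sits well above natural day-to-day variation in the index
#' while reliably catching shifts of that magnitude.
#'
#' @param reads Read tibble.
#' @param delta Flagging threshold in deg C (default 1.25).
#' @param window Length-2 integer: first and one-past-last index hour
#'   (default `c(5, 10)`, i.e. timestamps in \[05:00, 10:00)).
#' @param min_reads Minimal in-window readings for a day to participate.
#' @return Tibble `bird_id`, `day` (Date), `day_index`,
#'   `other_days_index`, `deficit` for every flagged pair (zero rows
#'   when none).
#' @export
detect_aberrant_days <- function(reads, delta = 1.25, window = c(5L, 10L),
                                 min_reads = 20L) {
  hr <- hour_of(reads$timestamp)
  morning <- reads[hr >= window[1] & hr < window[2], , drop = FALSE]
  empty <- tibble::tibble(
    bird_id = character(), day = as.Date(character()),
    day_index = numeric(), other_days_index = numeric(), deficit = numeric()
  )
  if (nrow(morning) == 0) return(empty)
  morning$day <- date_of(morning$timestamp)
  daily <- dplyr::summarise(
    dplyr::group_by(morning, .data$bird_id, .data$day),
    day_index = quantile(.data$tb, 0.75, names = FALSE),
    n_reads = dplyr::n(), .groups = "drop"
  )
  daily <- daily[daily$n_reads >= min_reads, , drop = FALSE]
  out <- dplyr::group_modify(dplyr::group_by(daily, .data$bird_id),
    function(d, key) {
      if (nrow(d) < 2) return(d[0, ])
      other <- vapply(seq_len(nrow(d)),
                      function(i) mean(d$day_index[-i]), numeric(1))
      d$other_days_index <- other
      d$deficit <- other - d$day_index
      d[d$deficit >= delta, ]
    })
  out <- dplyr::ungroup(out)
  if (nrow(out) == 0) return(empty)
  out[, c("bird_id", "day", "day_index", "other_days_index", "deficit")]
}

#' Remove flagged aberrant bird-days from a read stream
#'
#' Drops *all* reads (not just morning ones) on each flagged (bird, day).
#'
#' @param reads Read tibble.
#' @param flagged Output of [detect_aberrant_days()].
#' @return Filtered read tibble.
#' @export
remove_aberrant_days <- function(reads, flagged) {
  if (nrow(flagged) == 0) return(reads)
  key <- paste(reads$bird_id, date_of(reads$timestamp))
  bad <- paste(flagged$bird_id, flagged$day)
  reads[!key %in% bad, , drop = FALSE]
}
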