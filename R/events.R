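#' Segment a read stream into nest-box visits
#'
#' Tag readers only detect a bird while it is at the nest-box entrance, so
#' a contiguous run of reads is evidence of one presence bout ("visit").
#' Consecutive reads of the same bird separated by at most `gap_threshold`
#' seconds are assigned to the same visit; a larger gap starts a new one.
#' A single isolated read becomes a zero-duration visit with one read.
#'
#' @param reads Tibble with `bird_id`, `timestamp`, `tb`, sorted by
#'   (`bird_id`, `timestamp`). Unsorted input is an error: sorting is the
#'   caller's contract (see [read_pit_log()], which sorts).
#' @param gap_threshold Seconds; must exceed the 10 s tag re-read delay.
#'   Default 120 s: longer than the delay interval, shorter than a typical
#'   foraging trip.
#' @param resting_min_duration Passed to [flag_resting()].
#' @return Tibble of visits: `bird_id`, `visit_id` (per bird), `start`,
#'   `end`, `n_reads`, `duration` (s), `is_resting`.
#' @export
segment_visits <- function(reads, gap_threshold = 120,
                           resting_min_duration = 300) {
  if (gap_threshold <= 10) {
    abort("segment_visits: gap_threshold must exceed the 10 s read delay")
  }
  if (nrow(reads) == 0) {
    return(tibble::tibble(
      bird_id = character(), visit_id = integer(),
      start = as.POSIXct(character(), tz = ST_TZ),
      end = as.POSIXct(character(), tz = ST_TZ),
      n_reads = integer(), duration = numeric(), is_resting = logical()
    ))
  }
  grp <- split(seq_len(nrow(reads)), reads$bird_id)
  pieces <- lapply(grp, function(idx) {
    ts <- reads$timestamp[idx]
    if (is.unsorted(ts)) {
      abort("segment_visits: reads must be sorted by timestamp within bird")
    }
    gaps <- diff(as.numeric(ts))
    vid <- cumsum(c(1L, as.integer(gaps > gap_threshold)))
    starts <- ts[!duplicated(vid)]
    ends <- ts[!duplicated(vid, fromLast = TRUE)]
    n <- tabulate(vid)
    tibble::tibble(
      bird_id = reads$bird_id[idx[1]],
      visit_id = seq_along(starts),
      start = starts, end = ends, n_reads = n,
      duration = as.numeric(ends) - as.numeric(starts)
    )
  })
  visits <- dplyr::bind_rows(pieces)
  flag_resting(visits, resting_min_duration)
}

#' Flag resting visits
#'
#' A bird that stays at the nest-box for at least `resting_min_duration`
#' seconds (default 5 min, boundary inclusive) is considered to be resting
#' (or brooding; the two are not distinguishable from reader data). These
#' bouts define the observations from which the resting modal Tb and
#' heterothermy index are computed.
#'
#' @param visits Visit tibble from [segment_visits()].
#' @param resting_min_duration Seconds, default 300.
#' @return `visits` with `is_resting` set.
#' @export
flag_resting <- function(visits, resting_min_duration = 300) {
  visits$is_resting <- visits$duration >= resting_min_duration
  visits
}

#' Extract body temperatures observed during resting visits
#'
#' Returns exactly the reads whose timestamps fall inside a resting visit
#' of the same bird (intervals are closed on both ends).
#'
#' @param reads Read tibble.
#' @param visits Visit tibble with `is_resting`.
#' @return Tibble `bird_id`, `timestamp`, `tb` restricted to resting bouts.
#' @export
resting_observations <- function(reads, visits) {
  rest <- visits[visits$is_resting, , drop = FALSE]
  if (nrow(rest) == 0 || nrow(reads) == 0) {
    return(reads[0, c("bird_id", "timestamp", "tb")])
  }
  keep <- logical(nrow(reads))
  for (b in unique(rest$bird_id)) {
    vi <- rest[rest$bird_id == b, ]
    ri <- which(reads$bird_id == b)
    if (length(ri) == 0) next
    ts <- as.numeric(reads$timestamp[ri])
    st <- as.numeric(vi$start)[order(vi$start)]
    en <- as.numeric(vi$end)[order(vi$start)]
    pos <- findInterval(ts, st)
    inside <- pos > 0 & ts <= en[pmax(pos, 1)]
    keep[ri[inside]] <- TRUE
  }
  reads[keep, c("bird_id", "timestamp", "tb")]
}

#' Hourly nest-visit counts and per-chick feeding rate
#'
#' Counts, for one bird, the visits whose *start* falls in each clock hour
#' and divides by the brood size on that nestling day, yielding the
#' feeding rate in visits per hour per chick. Hours in `hours` with no
#' visits get rate 0; when `hours` is `NULL` only hours containing a visit
#' start appear.
#'
#' @param visits Visit tibble for one bird.
#' @param nests Nest metadata tibble (for `hatch_date` and brood sizes).
#' @param hours Optional POSIXct vector of hour starts to report
#'   (e.g. the hours with reader coverage).
#' @return Tibble `bird_id`, `hour_start`, `n_visits`, `brood_size`,
#'   `feeding_rate`. Hours whose brood size is zero are excluded with a
#'   warning (the per-chick rate is undefined).
#' @export
hourly_feeding_rate <- function(visits, nests, hours = NULL) {
  bird <- unique(visits$bird_id)
  if (length(bird) > 1) {
    abort("hourly_feeding_rate: supply visits for a single bird")
  }
  if (length(bird) == 0) {
    if (is.null(hours)) {
      return(tibble::tibble(bird_id = character(),
                            hour_start = as.POSIXct(character(), tz = ST_TZ),
                            n_visits = integer(), brood_size = integer(),
                            feeding_rate = numeric()))
    }
    abort("hourly_feeding_rate: empty visits but hours requested; no bird_id")
  }
  hour_start <- floor_hour(visits$start)
  counts <- dplyr::count(
    tibble::tibble(hour_start = hour_start), .data$hour_start,
    name = "n_visits"
  )
  if (!is.null(hours)) {
    counts <- dplyr::full_join(
      counts, tibble::tibble(hour_start = unique(floor_hour(hours))),
      by = "hour_start"
    )
    counts$n_visits[is.na(counts$n_visits)] <- 0L
    counts <- dplyr::arrange(counts, .data$hour_start)
  }
  hatch <- nests$hatch_date[nests$bird_id == bird]
  if (length(hatch) != 1) {
    abort(sprintf("hourly_feeding_rate: bird '%s' not in nest metadata", bird))
  }
  day <- as.integer(date_of(counts$hour_start) - hatch)
  bs <- vapply(day, function(d) brood_size(nests, bird, d), integer(1))
  zero <- bs == 0
  if (any(zero)) {
    warn(sprintf(
      "hourly_feeding_rate: %d hour(s) dropped for bird '%s' (brood size 0)",
      sum(zero), bird))
  }
  tibble::tibble(
    bird_id = bird,
    hour_start = counts$hour_start[!zero],
    n_visits = as.integer(counts$n_visits[!zero]),
    brood_size = bs[!zero],
    feeding_rate = counts$n_visits[!zero] / bs[!zero]
  )
}
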