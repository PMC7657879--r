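test_that("segment_visits groups reads by the gap rule", {
  reads <- make_reads("F01", c(0, 10, 20), c(41, 41.1, 41.2))
  v <- segment_visits(reads, gap_threshold = 60)
  expect_equal(nrow(v), 1)
  expect_equal(v$duration, 20)
  expect_equal(v$n_reads, 3L)

  reads2 <- make_reads("F01", c(0, 300), c(41, 41))
  v2 <- segment_visits(reads2, gap_threshold = 60)
  expect_equal(nrow(v2), 2)
  expect_equal(v2$duration, c(0, 0))
  expect_equal(v2$n_reads, c(1L, 1L))
  expect_false(any(v2$is_resting))  # zero-duration visits cannot be resting
})

test_that("segment_visits rejects unsorted input and small gap thresholds", {
  reads <- make_reads("F01", c(100, 0), c(41, 41))
  expect_error(segment_visits(reads, 60), "sorted")
  expect_error(segment_visits(make_reads("F01", 0, 41), 10), "exceed")
})

test_that("segmentation equals the exhaustive gap-split oracle on random streams", {
  set.seed(42)
  for (rep in 1:20) {
    gap <- sample(c(30, 60, 120, 240), 1)
    n <- sample(5:80, 1)
    secs <- sort(sample(0:5000, n)) * 1.0
    reads <- make_reads("F01", secs, rnorm(n, 41, 1))
    v <- segment_visits(reads, gap_threshold = gap)
    oracle <- oracle_segment(secs, gap)
    expect_equal(nrow(v), length(oracle))
    expect_equal(v$n_reads, lengths(oracle))
    expect_equal(as.numeric(v$start) - as.numeric(ts0(0)),
                 vapply(oracle, min, numeric(1)))
    # partition property: every read lands in exactly one visit
    expect_equal(sum(v$n_reads), n)
  }
})

test_that("visit count is monotone non-increasing in the gap threshold", {
  set.seed(7)
  secs <- sort(sample(0:3000, 60)) * 1.0
  reads <- make_reads("F01", secs, rnorm(60, 41, 1))
  counts <- vapply(c(20, 40, 80, 160, 320), function(g) {
    nrow(segment_visits(reads, gap_threshold = g))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("resting flag is boundary-inclusive at 5 min and monotone in the cut-off", {
  reads <- make_reads("F01", c(seq(0, 290, 10), 299, seq(1000, 1300, 10)),
                      rep(41, 62))
  v <- segment_visits(reads, gap_threshold = 120)
  expect_equal(v$duration, c(299, 300))
  expect_equal(v$is_resting, c(FALSE, TRUE))
  # monotonicity: raising the cut-off never adds resting visits
  r1 <- sum(flag_resting(v, 200)$is_resting)
  r2 <- sum(flag_resting(v, 300)$is_resting)
  r3 <- sum(flag_resting(v, 400)$is_resting)
  expect_true(r1 >= r2 && r2 >= r3)
})

test_that("resting_observations returns exactly the reads inside resting visits", {
  reads <- make_reads("F01", c(0, 10, 20, 500, 510, seq(1000, 1400, 10)),
                      41 + seq_len(46) / 100)
  v <- segment_visits(reads, gap_threshold = 120)
  ro <- resting_observations(reads, v)
  # only the 1000..1400 bout is >= 300 s
  expect_equal(nrow(ro), 41)
  expect_true(all(as.numeric(ro$timestamp) - as.numeric(ts0(0)) >= 1000))
  # no resting visits -> empty
  v0 <- flag_resting(v, 1e6)
  expect_equal(nrow(resting_observations(reads, v0)), 0)
})

test_that("resting_observations matches a filter-by-interval oracle on random data", {
  set.seed(99)
  secs <- sort(sample(0:20000, 300)) * 1.0
  reads <- make_reads("F01", secs, rnorm(300, 41, 1))
  v <- segment_visits(reads, gap_threshold = 90)
  ro <- resting_observations(reads, v)
  rest <- v[v$is_resting, ]
  inside <- vapply(seq_len(nrow(reads)), function(i) {
    any(reads$timestamp[i] >= rest$start & reads$timestamp[i] <= rest$end)
  }, logical(1))
  expect_equal(ro$tb, reads$tb[inside])
})

test_that("hourly feeding rate divides visit counts by brood size", {
  camp <- small_campaign(seed = 2)
  nests <- camp$nests
  bird <- nests$bird_id[1]
  day <- nests$hatch_date[1] + 6
  starts <- as.POSIXct(paste(day, "09:00:00"), tz = "UTC") +
    sort(runif(12, 0, 3599))
  visits <- tibble::tibble(
    bird_id = bird, visit_id = 1:12, start = starts, end = starts + 30,
    n_reads = 4L, duration = 30, is_resting = FALSE
  )
  nests$brood_d6[nests$bird_id == bird] <- 6L
  fr <- hourly_feeding_rate(visits, nests)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$n_visits, 12L)
  expect_equal(fr$feeding_rate, 2.0)
  # an hour with reader coverage but no visits reports rate zero
  fr2 <- hourly_feeding_rate(visits, nests,
                             hours = c(starts[1], starts[1] + 3600))
  expect_equal(fr2$feeding_rate[2], 0)
  # zero brood size: row excluded with a warning
  nests$brood_d6[nests$bird_id == bird] <- 0L
  expect_warning(fr3 <- hourly_feeding_rate(visits, nests), "brood size 0")
  expect_equal(nrow(fr3), 0)
})

test_that("simulated visit intensity matches the configured rate function", {
  cfg <- sim_config(n_birds = 8, hatch_spread = 2)
  camp <- simulate_campaign(cfg, seed = 8)
  v <- camp$truth$visits
  hr <- hour_of(v$start)
  v <- v[hr >= 5 & hr <= 20, ]
  for (grp in c("control", "trimmed")) {
    ids <- camp$nests$bird_id[camp$nests$treatment == grp]
    total <- 0; expected <- 0
    for (b in ids) {
      vb <- v[v$bird_id == b, ]
      if (nrow(vb) == 0) next
      day <- as.integer(date_of(vb$start) - camp$nests$hatch_date[
        camp$nests$bird_id == b])
      brood <- vapply(pmax(day, 0L), function(d) brood_size(camp$nests, b, d),
                      integer(1))
      # each bird-hour contributes lambda(ta) expected visits
      key <- paste(b, floor_hour(vb$start))
      per_hour <- split(seq_len(nrow(vb)), key)
      total <- total + nrow(vb)
      expected <- expected + sum(vapply(per_hour, function(ix) {
        true_visit_rate(vb$ta[ix[1]], grp, brood[ix[1]], cfg)
      }, numeric(1)))
    }
    # Poisson error on the pooled count (hours selected by having >= 1
    # visit, so allow a small upward bias on top of 3 SE)
    expect_lt(abs(total - expected), 3 * sqrt(expected) + 0.05 * expected)
  }
})
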