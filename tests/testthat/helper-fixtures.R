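# Small in-code fixtures and independent oracles used across test files.

ts0 <- function(s) as.POSIXct("2018-06-10 06:00:00", tz = "UTC") + s

make_reads <- function(bird_id, secs, tb) {
  tibble::tibble(
    bird_id = bird_id,
    timestamp = ts0(secs),
    tb = tb
  )
}

# a quick, small campaign for tests that need realistic structure but not
# the full default size
small_campaign <- function(seed = 1, ...) {
  cfg <- sim_config(n_birds = 6, hatch_spread = 4, ...)
  simulate_campaign(cfg, seed = seed)
}

write_csv_text <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  writeLines(lines, path)
  path
}

# --- independent oracles -------------------------------------------------

# exhaustive gap-split segmentation: split an ordered numeric time vector
# at every gap strictly greater than the threshold
oracle_segment <- function(times, gap) {
  if (length(times) == 0) return(list())
  groups <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] > gap) {
      groups[[length(groups) + 1]] <- cur
      cur <- t
    } else {
      cur <- c(cur, t)
    }
  }
  groups[[length(groups) + 1]] <- cur
  groups
}

# exhaustive frequency count over bins for the mode, lowest-bin tie-break
oracle_mode <- function(tbs, bin = 0.1) {
  bins <- round(tbs / bin)
  best_bin <- NULL
  best_n <- -1
  for (b in sort(unique(bins))) {
    n <- sum(bins == b)
    if (n > best_n) {  # strict: first (lowest) bin wins ties
      best_n <- n
      best_bin <- b
    }
  }
  best_bin * bin
}

# naive-loop heterothermy index
oracle_hi <- function(tbs, t_mod) {
  acc <- 0
  for (x in tbs) acc <- acc + (t_mod - x)^2
  sqrt(acc / (length(tbs) - 1))
}

# textbook Welch t statistic, df and p
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
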