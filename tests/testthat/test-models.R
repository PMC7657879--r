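# synthetic hour-level analysis tables with known structure
make_model_rows <- function(n_birds = 10, hours_per_bird = 60, seed = 1,
                            bird_sd = 0.3, noise = 0.3,
                            beta = c(ta = 0.02, feeding = 0.05)) {
  set.seed(seed)
  birds <- sprintf("F%02d", seq_len(n_birds))
  treatment <- rep(c("control", "trimmed"), length.out = n_birds)
  mage <- rep(c("ASY", "ASY", "SY", "SY"), length.out = n_birds)
  be <- rnorm(n_birds, 0, bird_sd)
  idx <- rep(seq_len(n_birds), each = hours_per_bird)
  n <- length(idx)
  ta <- runif(n, 6, 31)
  feeding <- runif(n, 0, 4)
  rows <- tibble::tibble(
    bird_id = birds[idx],
    treatment = treatment[idx],
    maternal_age = mage[idx],
    hour_start = floor_hour(ts0(seq_len(n) * 3600)),
    hour_of_day = sample(5:20, n, replace = TRUE),
    nestling_age = sample(3:14, n, replace = TRUE),
    ta = ta,
    feeding_rate = feeding,
    brood_size = sample(4:6, n, replace = TRUE),
    n_obs = 20L,
    hi_threshold = (42 + rnorm(n_birds, 0, 0.5))[idx]
  )
  rows$mean_tb <- 41 + beta["ta"] * ta + beta["feeding"] * feeding +
    0.01 * rows$nestling_age + be[idx] + rnorm(n, 0, noise)
  eta <- -4 + 0.15 * ta + be[idx]
  rows$n_hyper <- rbinom(n, rows$n_obs, plogis(eta))
  rows$any_hyper <- rows$n_hyper > 0
  rows$prop_hyper <- rows$n_hyper / rows$n_obs
  rows
}

test_that("orthogonal polynomial basis is orthonormal and reproduces polynomials", {
  set.seed(2)
  x <- runif(100, 5, 31)
  B <- orthogonal_poly_basis(x, 3)
  G <- crossprod(B)
  expect_equal(G, diag(3), ignore_attr = TRUE, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(B))), 1e-12)
  # projecting a known cubic onto [1, basis] reproduces it exactly
  y <- 2 - 0.5 * x + 0.03 * x^2 + 0.001 * x^3
  fit <- lm(y ~ B)
  expect_lt(max(abs(fitted(fit) - y)), 1e-8)
  # degree must stay below the number of distinct values
  expect_equal(ncol(orthogonal_poly_basis(rep(c(1, 2), 5), 1)), 1)
  expect_error(orthogonal_poly_basis(rep(c(1, 2), 5), 2), "distinct")
})

test_that("with no between-bird variance the LMM equals weighted least squares", {
  rows <- make_model_rows(bird_sd = 0, seed = 7)
  fit <- fit_lmm_tb(rows, ta_degree = 3, weights_by = "none")
  rows$treatment <- factor(rows$treatment, levels = c("control", "trimmed"))
  rows$maternal_age <- factor(rows$maternal_age, levels = c("ASY", "SY"))
  ref <- lm(mean_tb ~ treatment + poly(ta, 3) + feeding_rate + nestling_age +
              maternal_age + hour_of_day + brood_size +
              treatment:poly(ta, 3) + treatment:feeding_rate, data = rows)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("k-fold duplicated rows with weights 1/k reproduce the coefficients", {
  # raw polynomial coding: the orthonormal basis is sample-dependent, so
  # duplication would change the poly parameterization (not the fit)
  rows <- make_model_rows(bird_sd = 0, seed = 13, hours_per_bird = 40)
  f1 <- fit_lmm_tb(rows, ta_degree = 2, weights = rep(1, nrow(rows)),
                   raw_poly = TRUE)
  k <- 3
  dup <- rows[rep(seq_len(nrow(rows)), k), ]
  f2 <- fit_lmm_tb(dup, ta_degree = 2, weights = rep(1 / k, nrow(dup)),
                   raw_poly = TRUE)
  # variance components are re-estimated on the duplicated data, so the
  # fixed effects agree to the precision of that ratio, not exactly
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("likelihood-ratio test follows its defining formula and contracts", {
  # identical fits: statistic 0, p = 1
  same <- lr_test(-50, -50, df_small = 3, df_big = 5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # formula oracle on random values
  set.seed(11)
  for (i in 1:20) {
    ll1 <- -runif(1, 10, 200)
    ll2 <- ll1 + runif(1, 0, 30)
    d <- sample(1:4, 1)
    out <- lr_test(ll1, ll2, df_small = 5, df_big = 5 + d)
    expect_equal(out$statistic, 2 * (ll2 - ll1))
    expect_equal(out$df, d)
    expect_equal(out$p_value, pchisq(2 * (ll2 - ll1), d, lower.tail = FALSE))
  }
  expect_error(lr_test(-50, -49, df_small = 5, df_big = 5), "nested")
  expect_error(lr_test(-50, -60, df_small = 5, df_big = 7), "decreased")
})

test_that("LR statistic is invariant to affine recoding of shared covariates", {
  rows <- make_model_rows(seed = 17)
  f1s <- fit_lmm_tb(rows, ta_degree = 1)
  f1b <- fit_lmm_tb(rows, ta_degree = 2)
  lr1 <- lr_test(f1s, f1b)
  rows2 <- rows
  rows2$feeding_rate <- 2 * rows2$feeding_rate + 1
  rows2$nestling_age <- rows2$nestling_age - 8
  f2s <- fit_lmm_tb(rows2, ta_degree = 1)
  f2b <- fit_lmm_tb(rows2, ta_degree = 2)
  lr2 <- lr_test(f2s, f2b)
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-6)
})

test_that("AIC follows 2k - 2logL and penalises an idle parameter by exactly 2", {
  expect_equal(model_aic(0, 0), 0)
  set.seed(3)
  for (i in 1:20) {
    ll <- -runif(1, 10, 300)
    k <- sample(1:20, 1)
    expect_equal(model_aic(ll, k), 2 * k - 2 * ll)
    expect_equal(model_aic(ll, k + 1) - model_aic(ll, k), 2)
  }
})

test_that("threshold comparison is a two-tailed Welch t-test", {
  same <- t_test_thresholds(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(5:12, 1), 42.8, 1)
    y <- rnorm(sample(5:12, 1), 43.0, 1.3)
    got <- t_test_thresholds(x, y)
    ref <- oracle_welch(x, y)
    expect_equal(got$statistic, ref$t, tolerance = 1e-12)
    expect_equal(got$df, ref$df, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
    expect_false(got$df == round(got$df) && var(x) != var(y))
  }
})

test_that("occurrence model with no bird variance matches plain logistic IRLS", {
  rows <- make_model_rows(bird_sd = 0, seed = 23, n_birds = 12,
                          hours_per_bird = 400)
  fit <- fit_any_hyper(rows)
  expect_true(fit$converged)
  rows$treatment <- factor(rows$treatment, levels = c("control", "trimmed"))
  rows$maternal_age <- factor(rows$maternal_age, levels = c("ASY", "SY"))
  ref <- glm(any_hyper ~ treatment + ta + feeding_rate + nestling_age +
               maternal_age + hour_of_day + hi_threshold + treatment:ta,
             family = binomial(), data = rows)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 5e-3)
  # degenerate response is rejected
  rows0 <- rows
  rows0$any_hyper <- FALSE
  expect_error(fit_any_hyper(rows0), "constant")
})

test_that("occurrence model recovers a known Ta log-odds slope", {
  covered <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    rows <- make_model_rows(bird_sd = 0.4, seed = 1000 + s, n_birds = 16,
                            hours_per_bird = 50)
    # hour-level Bernoulli response with the target log-odds slope on Ta
    set.seed(2000 + s)
    be <- rnorm(16, 0, 0.4)
    rows$any_hyper <- runif(nrow(rows)) <
      plogis(-4 + 0.15 * rows$ta + be[as.integer(factor(rows$bird_id))])
    fit <- fit_any_hyper(rows)
    co <- fit$coefficients
    i <- which(co$term == "ta")
    if (isTRUE(abs(co$estimate[i] - 0.15) <= 2 * co$std_error[i])) {
      covered <- covered + 1
    }
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("positive-part model honours its contracts and degenerate cases", {
  rows <- make_model_rows(seed = 29)
  rows0 <- rows
  rows0$any_hyper <- FALSE
  expect_error(fit_prop_hyper(rows0), "empty positive")
  bad <- rows
  bad$prop_hyper[bad$any_hyper][1] <- 1.5
  expect_error(fit_prop_hyper(bad), "\\(0, 1\\]")
  expect_error(fit_prop_hyper(rows, power = 2.5), "between 1 and 2")
  # constant response -> all slopes effectively zero
  const <- rows[rows$any_hyper, ]
  set.seed(1)
  const$prop_hyper <- pmin(0.3 + abs(rnorm(nrow(const), 0, 0.01)), 1)
  const$any_hyper <- TRUE
  fit <- suppressWarnings(fit_prop_hyper(const))
  co <- fit$coefficients
  slopes <- co$estimate[!co$term %in% "(Intercept)"]
  expect_lt(max(abs(slopes), na.rm = TRUE), 0.02)
  expect_equal(co$estimate[co$term == "(Intercept)"], log(0.3),
               tolerance = 0.1)
})

test_that("as the variance power approaches 1 the fit matches Poisson-family IRLS", {
  rows <- make_model_rows(bird_sd = 0, seed = 31, n_birds = 12,
                          hours_per_bird = 80)
  rows <- rows[rows$any_hyper, ]
  fit <- fit_prop_hyper(rows, power = 1 + 1e-6)
  rows$treatment <- factor(rows$treatment, levels = c("control", "trimmed"))
  rows$maternal_age <- factor(rows$maternal_age, levels = c("ASY", "SY"))
  ref <- suppressWarnings(glm(
    prop_hyper ~ treatment + ta + feeding_rate + nestling_age +
      maternal_age + hour_of_day + hi_threshold + treatment:ta,
    family = quasipoisson(link = "log"), data = rows))
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 5e-3)
})

test_that("marginal predictions invert the link and average over the grid", {
  rows <- make_model_rows(bird_sd = 0.2, seed = 37, n_birds = 12,
                          hours_per_bird = 60)
  fit <- fit_any_hyper(rows)
  at <- tibble::tibble(
    treatment = c("control", "trimmed"), ta = 25, feeding_rate = 2,
    nestling_age = 8, maternal_age = "ASY", hour_of_day = 12,
    hi_threshold = 42
  )
  pred <- marginal_predictions(fit, at)
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  eta_control <- co["(Intercept)"] + co["ta"] * 25 + co["feeding_rate"] * 2 +
    co["nestling_age"] * 8 + co["hour_of_day"] * 12 + co["hi_threshold"] * 42
  expect_equal(pred$prediction[1], unname(plogis(eta_control)),
               tolerance = 1e-8)
  expect_true(all(pred$ci_lower <= pred$prediction &
                    pred$prediction <= pred$ci_upper))
  # grid averaging equals the mean of per-cell predictions
  grid <- tidyr::crossing(
    treatment = c("control", "trimmed"), ta = c(20, 25, 30),
    feeding_rate = 2, nestling_age = 8, maternal_age = "ASY",
    hour_of_day = 12, hi_threshold = 42
  )
  per_cell <- marginal_predictions(fit, grid)
  avg <- marginal_predictions(fit, grid, average_over = "treatment")
  manual <- tapply(per_cell$prediction, per_cell$treatment, mean)
  expect_equal(avg$prediction, as.numeric(manual[avg$treatment]),
               tolerance = 1e-10)
  # identity link: prediction at the data mean equals the linear predictor
  lfit <- fit_lmm_tb(rows, ta_degree = 2)
  lp <- marginal_predictions(lfit, rows[1:5, ])
  expect_true(all(is.finite(lp$prediction)))
  expect_true(all(lp$ci_lower < lp$ci_upper))
})
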