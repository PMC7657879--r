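#' @title Model-fit container
#' @description Every fitting function in the package returns a
#' `st_model_fit`: a uniform summary holding the named coefficient table
#' (estimate, standard error, Wald 95% CI, statistic, p-value), the
#' log-likelihood and parameter count, the fitting method and a
#' convergence flag, plus the underlying fitted model for prediction.
#' @param name Model label.
#' @param coefficients Tibble with columns `term`, `estimate`, `std_error`,
#'   `ci_lower`, `ci_upper`, `statistic`, `p_value`.
#' @param log_likelihood Numeric scalar.
#' @param n_parameters Integer: fixed effects + variance components.
#' @param method Estimation method label.
#' @param converged Logical.
#' @param model The underlying fitted model object.
#' @param notes Character vector of diagnostics.
#' @return An object of class `st_model_fit`.
#' @keywords internal
new_model_fit <- function(name, coefficients, log_likelihood, n_parameters,
                          method, converged, model = NULL,
                          notes = character()) {
  structure(
    list(
      name = name,
      coefficients = coefficients,
      log_likelihood = as.numeric(log_likelihood),
      n_parameters = as.integer(n_parameters),
      method = method,
      converged = isTRUE(converged),
      model = model,
      notes = notes
    ),
    class = "st_model_fit"
  )
}

#' @export
print.st_model_fit <- function(x, ...) {
  cat(sprintf("<%s>  method: %s  logLik: %.2f  parameters: %d  converged: %s\n",
              x$name, x$method, x$log_likelihood, x$n_parameters,
              x$converged))
  print(x$coefficients, n = Inf)
  if (length(x$notes) > 0) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Wald coefficient table from estimates and a covariance matrix;
# statistics are z (normal reference), CIs are estimate +/- 1.96 SE.
wald_table <- function(beta, V, level = 0.95) {
  se <- sqrt(diag(as.matrix(V)))
  z <- beta / se
  zc <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    ci_lower = unname(beta - zc * se),
    ci_upper = unname(beta + zc * se),
    statistic = unname(z),
    p_value = unname(2 * pnorm(-abs(z)))
  )
}

#' Orthonormal polynomial basis
#'
#' Degree-1..k polynomial columns that are mutually orthonormal over the
#' sample (the degree-0 constant is excluded), as produced by orthogonal
#' polynomial coding. Orthonormal coding keeps polynomial coefficient
#' estimates on a comparable, near-unit scale and makes order-selection
#' tests well conditioned; raw powers are available via `raw = TRUE`.
#'
#' @param x Numeric vector.
#' @param degree Polynomial degree (1--3 in this pipeline).
#' @param raw Use raw powers instead of the orthonormal basis.
#' @return Matrix with `degree` columns and a `"coefs"` attribute for
#'   prediction at new `x`.
#' @export
orthogonal_poly_basis <- function(x, degree, raw = FALSE) {
  if (degree >= length(unique(x))) {
    abort("orthogonal_poly_basis: degree must be less than the number of distinct values")
  }
  stats::poly(x, degree = degree, raw = raw)
}

# per-bird (or per-hour-of-day) inverse-variance weights for the Tb model,
# normalized to mean 1; groups with undefined or zero variance get the
# largest finite weight so they are retained, not dominant.
feeding_rate_weights <- function(rows, weights_by = c("bird", "hour", "none")) {
  weights_by <- match.arg(weights_by)
  if (weights_by == "none") return(rep(1, nrow(rows)))
  key <- if (weights_by == "bird") rows$bird_id else rows$hour_of_day
  v <- tapply(rows$feeding_rate, key, var)
  w_grp <- 1 / v
  finite <- is.finite(w_grp) & w_grp > 0
  if (!any(finite)) return(rep(1, nrow(rows)))
  w_grp[!finite] <- max(w_grp[finite])
  w <- unname(w_grp[as.character(key)])
  w / mean(w)
}

# drop model terms whose factor has < 2 levels in the data (degenerate
# simulated designs); returns the terms that survive
.two_level <- function(rows, col) length(unique(rows[[col]])) >= 2

lmm_tb_formula <- function(rows, ta_degree, raw_poly) {
  ta_term <- sprintf("poly(ta, %d, raw = %s)", ta_degree,
                     if (raw_poly) "TRUE" else "FALSE")
  terms <- c("treatment", ta_term, "feeding_rate", "nestling_age",
             "maternal_age", "hour_of_day", "brood_size",
             paste0("treatment:", ta_term), "treatment:feeding_rate")
  if (!.two_level(rows, "maternal_age")) {
    terms <- setdiff(terms, "maternal_age")
  }
  if (!.two_level(rows, "treatment")) {
    terms <- setdiff(terms, grep("treatment", terms, value = TRUE))
  }
  stats::as.formula(paste("mean_tb ~", paste(terms, collapse = " + "),
                          "+ (1 | bird_id)"))
}

#' Weighted polynomial mixed model for hourly body temperature
#'
#' Gaussian random-intercept (per bird) model of mean hourly Tb with
#' treatment, an orthogonal polynomial in ambient temperature (degree
#' 1--3), per-chick feeding rate, nestling age, maternal age, hour of day
#' and brood size as fixed effects, plus treatment x Ta-polynomial and
#' treatment x feeding-rate interactions. Observations are weighted by
#' the inverse variance of feeding rate (heteroskedasticity: feeding-rate
#' residual variance shrinks with the rate itself), grouped per bird by
#' default.
#'
#' @param rows Filtered bird-hour tibble.
#' @param ta_degree Polynomial degree for Ta, 1, 2 or 3 (default 3).
#' @param REML Use REML (for reporting) instead of ML (for likelihood-
#'   ratio comparisons). Default `FALSE` (ML).
#' @param weights_by `"bird"` (default), `"hour"` (hour-of-day bins) or
#'   `"none"`.
#' @param weights Optional explicit numeric weight vector overriding
#'   `weights_by`.
#' @param raw_poly Use raw polynomial coding instead of orthonormal.
#' @return A [`st_model_fit`][new_model_fit].
#' @export
fit_lmm_tb <- function(rows, ta_degree = 3, REML = FALSE,
                       weights_by = "bird", weights = NULL,
                       raw_poly = FALSE) {
  stopifnot(ta_degree %in% 1:3)
  if (length(unique(rows$bird_id)) < 2) {
    abort("fit_lmm_tb: need at least 2 birds")
  }
  rows <- prep_factor_cols(rows)
  w <- if (is.null(weights)) feeding_rate_weights(rows, weights_by) else weights
  if (any(w <= 0)) abort("fit_lmm_tb: weights must be positive")
  form <- lmm_tb_formula(rows, ta_degree, raw_poly)
  rows$..w <- w
  fit <- lme4::lmer(form, data = rows, weights = ..w, REML = REML)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv <- fit@optinfo$conv$opt == 0 && length(msgs) == 0
  ll <- logLik(fit)
  new_model_fit(
    name = sprintf("tb_lmm_ta%d", ta_degree),
    coefficients = wald_table(lme4::fixef(fit), vcov(fit)),
    log_likelihood = as.numeric(ll),
    n_parameters = attr(ll, "df"),
    method = if (REML) "REML" else "ML",
    converged = conv,
    model = fit,
    notes = as.character(msgs)
  )
}

get_ll_df <- function(x, df = NULL, what = "lr_test") {
  if (inherits(x, "st_model_fit")) {
    list(ll = x$log_likelihood, df = x$n_parameters, method = x$method)
  } else if (is.numeric(x) && length(x) == 1) {
    if (is.null(df)) {
      abort(sprintf("%s: supply the parameter count for a numeric log-likelihood",
                    what))
    }
    list(ll = x, df = as.integer(df), method = "ML")
  } else {
    abort(sprintf("%s: expected a st_model_fit or a numeric log-likelihood",
                  what))
  }
}

#' Likelihood-ratio test between nested ML fits
#'
#' `statistic = 2 (logL_big - logL_small)`, with degrees of freedom equal
#' to the difference in parameter counts and a chi-squared upper-tail
#' p-value. Both fits must be on the ML scale and strictly nested
#' (parameter count increasing); a log-likelihood that *decreases* in the
#' bigger model beyond numerical tolerance is an error.
#'
#' @param fit_small,fit_big [`st_model_fit`][new_model_fit] objects, or
#'   bare numeric log-likelihoods (then give `df_small` / `df_big`).
#' @param df_small,df_big Parameter counts when log-likelihoods are given
#'   as numbers.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit_small, fit_big, df_small = NULL, df_big = NULL) {
  s <- get_ll_df(fit_small, df_small)
  b <- get_ll_df(fit_big, df_big)
  if (identical(s$method, "REML") || identical(b$method, "REML")) {
    abort("lr_test: fits must be on the ML scale (REML log-likelihoods are not comparable)")
  }
  if (b$df <= s$df) {
    abort("lr_test: models not nested (parameter count must increase)")
  }
  stat <- 2 * (b$ll - s$ll)
  if (stat < -1e-6) {
    abort("lr_test: log-likelihood decreased in the larger model; fits are not nested or did not converge")
  }
  stat <- max(stat, 0)
  df <- b$df - s$df
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2 k - 2 logL` with `k` the parameter count (fixed effects plus
#' variance components).
#'
#' @param fit A [`st_model_fit`][new_model_fit] or a numeric
#'   log-likelihood.
#' @param n_parameters Parameter count when `fit` is numeric.
#' @return Numeric AIC.
#' @export
model_aic <- function(fit, n_parameters = NULL) {
  x <- get_ll_df(fit, n_parameters, what = "model_aic")
  2 * x$df - 2 * x$ll
}

#' Welch t-test on hyperthermia thresholds
#'
#' Two-tailed independent-sample t-test (unequal variances; the
#' fractional degrees of freedom signal the Welch correction) comparing
#' per-bird hyperthermia thresholds between treatment groups. The
#' statistic is for control minus trimmed.
#'
#' @param control,trimmed Numeric vectors of per-bird thresholds (deg C).
#' @return Tibble with `statistic`, `df`, `ci_lower`, `ci_upper`,
#'   `p_value`, `mean_control`, `mean_trimmed`.
#' @export
t_test_thresholds <- function(control, trimmed) {
  tt <- t.test(control, trimmed, var.equal = FALSE,
               alternative = "two.sided")
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    ci_lower = tt$conf.int[1],
    ci_upper = tt$conf.int[2],
    p_value = tt$p.value,
    mean_control = mean(control),
    mean_trimmed = mean(trimmed)
  )
}

hurdle_formula <- function(rows, response) {
  terms <- c("treatment", "ta", "feeding_rate", "nestling_age",
             "maternal_age", "hour_of_day", "hi_threshold", "treatment:ta")
  if (!.two_level(rows, "maternal_age")) terms <- setdiff(terms, "maternal_age")
  if (!.two_level(rows, "treatment")) {
    terms <- setdiff(terms, c("treatment", "treatment:ta"))
  }
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + "),
                          "+ (1 | bird_id)"))
}

prep_factor_cols <- function(rows) {
  if ("treatment" %in% names(rows)) {
    rows$treatment <- factor(rows$treatment, levels = c("control", "trimmed"))
    rows$treatment <- droplevels(rows$treatment)
  }
  if ("maternal_age" %in% names(rows)) {
    rows$maternal_age <- factor(rows$maternal_age, levels = c("ASY", "SY"))
    rows$maternal_age <- droplevels(rows$maternal_age)
  }
  rows
}

#' Occurrence part of the hyperthermia hurdle model
#'
#' Logistic random-intercept model (Laplace-approximated ML) of whether a
#' bird experienced at least one hyperthermic observation within an hour.
#' Fixed effects: treatment, Ta, per-chick feeding rate, nestling age,
#' maternal age, hour of day, the bird's HI threshold, and treatment x Ta.
#' Coefficients are reported as log-odds.
#'
#' @param rows Filtered bird-hour tibble.
#' @return A [`st_model_fit`][new_model_fit]; apparent complete
#'   separation is flagged in `notes` and `converged`.
#' @export
fit_any_hyper <- function(rows) {
  rows <- prep_factor_cols(rows)
  y <- as.integer(rows$any_hyper)
  if (all(y == 0) || all(y == 1)) {
    abort("fit_any_hyper: response is constant (all 0 or all 1)")
  }
  form <- hurdle_formula(rows, "any_hyper")
  fit <- glmmTMB::glmmTMB(form, data = rows, family = stats::binomial())
  beta <- glmmTMB::fixef(fit)$cond
  V <- vcov(fit)$cond
  notes <- character()
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  if (any(abs(beta[-1]) > 15, na.rm = TRUE)) {
    notes <- c(notes, "possible complete separation: |log-odds| > 15")
    conv <- FALSE
  }
  new_model_fit(
    name = "any_hyper_glmm",
    coefficients = wald_table(beta, V),
    log_likelihood = as.numeric(logLik(fit)),
    n_parameters = attr(logLik(fit), "df"),
    method = "Laplace-ML (binomial)",
    converged = conv,
    model = fit,
    notes = notes
  )
}

#' Positive part of the hyperthermia hurdle model
#'
#' Model of the proportion of observations that were hyperthermic within
#' hours where hyperthermia occurred at all: a Tweedie
#' (power-variance, log link) random-intercept model, which captures the
#' Poisson-like right-skew of small positive proportions. The variance
#' power is fixed at `power` (default 1.5, the midpoint of the
#' compound-Poisson range) unless `estimate_power = TRUE`. Same fixed
#' effects as [fit_any_hyper()]. Within-bird serial correlation beyond
#' the random intercept is not modelled (documented caveat).
#'
#' @param rows Bird-hour tibble; only rows with `any_hyper` true are
#'   used, and an empty positive subset is an error.
#' @param power Tweedie variance power in (1, 2).
#' @param estimate_power Estimate the power from the data instead.
#' @return A [`st_model_fit`][new_model_fit].
#' @export
fit_prop_hyper <- function(rows, power = 1.5, estimate_power = FALSE) {
  rows <- prep_factor_cols(rows)
  rows <- rows[rows$any_hyper, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort("fit_prop_hyper: no hours with hyperthermia (empty positive subset)")
  }
  if (any(rows$prop_hyper <= 0 | rows$prop_hyper > 1)) {
    abort("fit_prop_hyper: responses must lie in (0, 1]")
  }
  if (!estimate_power && (power <= 1 || power >= 2)) {
    abort("fit_prop_hyper: fixed power must lie strictly between 1 and 2")
  }
  form <- hurdle_formula(rows, "prop_hyper")
  args <- list(formula = form, data = rows,
               family = glmmTMB::tweedie(link = "log"))
  if (!estimate_power) {
    args$start <- list(psi = qlogis(power - 1))
    args$map <- list(psi = factor(NA))
  }
  fit <- do.call(glmmTMB::glmmTMB, args)
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  method <- if (estimate_power) {
    "Laplace-ML (Tweedie, power estimated)"
  } else {
    sprintf("Laplace-ML (Tweedie, power fixed at %g)", power)
  }
  new_model_fit(
    name = "prop_hyper_glmm",
    coefficients = wald_table(glmmTMB::fixef(fit)$cond, vcov(fit)$cond),
    log_likelihood = as.numeric(logLik(fit)),
    n_parameters = attr(logLik(fit), "df"),
    method = method,
    converged = conv,
    model = fit,
    notes = "random intercept per bird; residual serial correlation not modelled"
  )
}

#' Population-level (marginal) predictions on a reference grid
#'
#' Predicts the response at the covariate settings in `at`, with random
#' effects set to zero (population level) and a delta-method Wald CI on
#' the link scale, back-transformed through the inverse link. When
#' `average_over` names grouping columns of `at`, predictions are
#' averaged within each group: the reported prediction is the mean of the
#' per-cell response predictions, and the CI is computed for the averaged
#' linear predictor.
#'
#' @param fit A [`st_model_fit`][new_model_fit] from this package.
#' @param at Data frame of covariate settings (the reference grid).
#' @param average_over Optional character vector of columns of `at` that
#'   define groups to average within; `NULL` (default) predicts per row.
#' @param level Confidence level, default 0.95.
#' @return Tibble: the `at` columns (or `average_over` groups) plus
#'   `prediction`, `ci_lower`, `ci_upper`.
#' @export
marginal_predictions <- function(fit, at, average_over = NULL, level = 0.95) {
  model <- fit$model
  if (is.null(model)) abort("marginal_predictions: fit carries no model object")
  at <- tibble::as_tibble(at)
  at <- prep_factor_cols(at)
  zc <- qnorm(1 - (1 - level) / 2)
  if (inherits(model, "glmmTMB")) {
    fam <- stats::family(model)
    if (!"bird_id" %in% names(at)) at$bird_id <- NA_character_
    pr <- predict(model, newdata = at, type = "link", se.fit = TRUE,
                  re.form = NA, allow.new.levels = TRUE)
    eta <- as.numeric(pr$fit)
    X <- NULL
    se <- as.numeric(pr$se.fit)
    linkinv <- fam$linkinv
  } else if (inherits(model, "merMod")) {
    tt <- delete.response(terms(model, fixed.only = TRUE))
    xlev <- stats::.getXlevels(tt, model.frame(model, fixed.only = TRUE))
    mf <- model.frame(tt, at, xlev = xlev)
    X <- model.matrix(tt, mf)
    beta <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    eta <- as.numeric(X %*% beta)
    se <- sqrt(rowSums((X %*% V) * X))
    linkinv <- identity
  } else {
    abort("marginal_predictions: unsupported model class")
  }
  if (is.null(average_over)) {
    out <- at
    out$prediction <- linkinv(eta)
    out$ci_lower <- linkinv(eta - zc * se)
    out$ci_upper <- linkinv(eta + zc * se)
    return(out)
  }
  key <- interaction(at[average_over], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(at)), key)
  rows <- lapply(groups, function(idx) {
    mean_eta <- mean(eta[idx])
    if (!is.null(X)) {
      a <- colMeans(X[idx, , drop = FALSE])
      se_m <- sqrt(as.numeric(t(a) %*% as.matrix(vcov(model)) %*% a))
    } else {
      # conservative: average per-cell SEs (covariances unavailable here)
      se_m <- mean(se[idx])
    }
    cbind(
      at[idx[1], average_over, drop = FALSE],
      tibble::tibble(
        prediction = mean(linkinv(eta[idx])),
        ci_lower = linkinv(mean_eta - zc * se_m),
        ci_upper = linkinv(mean_eta + zc * se_m)
      )
    )
  })
  tibble::as_tibble(dplyr::bind_rows(rows))
}
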