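#' Closed-form conditional moments of the response families
#'
#' Mean and variance of `T | x` for each family, used by the pseudo-R^2
#' Monte Carlo. All three families admit Gamma-function closed forms:
#' Weibull with scale `s = (scale * exp(lp))^(-1/shape)` has
#' `E T^r = s^r * Gamma(1 + r/shape)`; the lognormal uses the usual
#' `exp(mu + sd^2/2)` formulas; the generalized gamma with scale
#' `a' = scale * exp(lp)` has `E T^r = a'^r * Gamma(k + r/b) / Gamma(k)`.
#'
#' @param model a `response_model`.
#' @param lp linear predictor vector.
#' @param x1 binary vector (generalized gamma only).
#' @return list with numeric vectors `mean` and `var`.
#' @export
conditional_moments <- function(model, lp, x1 = NULL) {
  stopifnot(inherits(model, "response_model"))
  out <- switch(model$family,
    weibull_ph = {
      s <- (model$scale * exp(lp))^(-1 / model$shape)
      g1 <- gamma(1 + 1 / model$shape)
      g2 <- gamma(1 + 2 / model$shape)
      list(mean = s * g1, var = s^2 * (g2 - g1^2))
    },
    lognormal_aft = {
      mu <- model$intercept + lp
      s2 <- model$sd^2
      list(mean = exp(mu + s2 / 2), var = (exp(s2) - 1) * exp(2 * mu + s2))
    },
    gen_gamma = {
      if (is.null(x1)) stop_named("sfb_missing_x1",
                                  "x1 is required for the gen_gamma family")
      ap <- model$scale * exp(lp)
      k <- ifelse(x1 == 1, model$k1, model$k0)
      b <- model$shape
      r1 <- exp(lgamma(k + 1 / b) - lgamma(k))
      r2 <- exp(lgamma(k + 2 / b) - lgamma(k))
      list(mean = ap * r1, var = ap^2 * (r2 - r1^2))
    })
  if (any(!is.finite(out$mean)) || any(!is.finite(out$var)))
    stop_named("sfb_nonfinite_moments",
               "non-finite conditional moments for family %s (check parameters)",
               model$family)
  out
}

#' Pseudo-R^2 and signal-to-noise ratio of a data-generating mechanism
#'
#' Estimates `R^2 = Var(E(T|X)) / (Var(E(T|X)) + E(Var(T|X)))` by Monte
#' Carlo over covariate draws, with the conditional moments taken in closed
#' form, and reports `SNR = R^2 / (1 - R^2)`. Population (denominator `n`)
#' variance is used so that small exhaustive designs give exact values.
#'
#' @param model a `response_model`.
#' @param spec an [lp_spec()].
#' @param extra_level extra-variable level for the covariate draw.
#' @param n number of outer Monte Carlo covariate draws.
#' @param seed optional integer seed (local).
#' @param X optional explicit covariate matrix (overrides `n`/`extra_level`);
#'   the empirical distribution of its rows is then treated as the covariate
#'   law, allowing exact two-point designs in tests.
#' @return object of class `snr_report` with fields `r2`, `snr`, `mc_config`.
#' @export
pseudo_r2 <- function(model, spec, extra_level = "baseline", n = 1e5,
                      seed = NULL, X = NULL) {
  if (is.null(X)) X <- gen_covariates(n, extra_level, seed = seed)
  lp <- linear_predictor(X, spec)
  mom <- conditional_moments(model, lp, x1 = X[, "x1"])
  var_e <- mean((mom$mean - mean(mom$mean))^2)
  e_var <- mean(mom$var)
  r2 <- var_e / (var_e + e_var)
  structure(list(r2 = r2, snr = r2 / (1 - r2),
                 mc_config = list(n = nrow(X), seed = seed)),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report: r2 = %.4f, snr = %.4f (n = %d)>\n",
              x$r2, x$snr, x$mc_config$n))
  invisible(x)
}

#' Calibrate the signal scale to a target signal-to-noise ratio
#'
#' Rescales all linear-predictor coefficients through the single
#' `signal_scale` multiplier until the SNR of the mechanism matches
#' `target_snr`. A fixed covariate sample (common random numbers) makes the
#' SNR a deterministic function of the scale; monotonicity is checked on a
#' coarse grid before a bracketed root search.
#'
#' @param model a `response_model`.
#' @param spec an [lp_spec()]; its `signal_scale` is the starting value.
#' @param target_snr target SNR (> 0).
#' @param tol tolerance on `|snr - target_snr|`.
#' @param extra_level,n,seed,X covariate draw controls as in [pseudo_r2()].
#' @param scale_range multiplier search bracket (relative to the current
#'   `signal_scale`).
#' @return list with the (unchanged) `model`, the rescaled `spec`, the
#'   achieved `snr_report` and the scale `multiplier`.
#' @export
calibrate_signal <- function(model, spec, target_snr = 1, tol = 0.02,
                             extra_level = "baseline", n = 1e5, seed = NULL,
                             X = NULL, scale_range = c(1e-4, 8)) {
  stopifnot(target_snr > 0, tol > 0)
  if (is.null(X)) X <- gen_covariates(n, extra_level, seed = seed)
  snr_at <- function(mult) {
    sp <- spec
    sp$signal_scale <- spec$signal_scale * mult
    tryCatch(pseudo_r2(model, sp, X = X)$snr, error = function(e) NA_real_)
  }
  grid <- exp(seq(log(scale_range[1]), log(scale_range[2]), length.out = 9))
  vals <- vapply(grid, snr_at, numeric(1))
  fin <- is.finite(vals)
  if (sum(fin) < 2)
    stop_named("sfb_no_bracket",
               "snr is not computable over the multiplier search range")
  grid <- grid[fin]; vals <- vals[fin]
  # snr must be monotone in the scale over the searched range; the
  # direction may be either (crossing-hazard mechanisms carry signal at
  # scale zero and can lose snr as the scale grows)
  incr <- all(diff(vals) > -1e-10)
  decr <- all(diff(vals) < 1e-10)
  if (!incr && !decr)
    stop_named("sfb_snr_not_monotone",
               "snr is not monotone in signal_scale over the search grid: %s",
               paste(sprintf("s=%.3g:snr=%.4g", grid, vals), collapse = "; "))
  lo <- min(vals); hi <- max(vals)
  if (target_snr < lo || target_snr > hi)
    stop_named("sfb_no_bracket",
               "target snr %.4g outside achievable range [%.4g, %.4g] for multipliers in [%g, %g]",
               target_snr, lo, hi, grid[1], grid[length(grid)])
  root <- uniroot(function(m) snr_at(m) - target_snr,
                  interval = range(grid), tol = 1e-9)
  mult <- root$root
  spec$signal_scale <- spec$signal_scale * mult
  rep <- pseudo_r2(model, spec, X = X)
  if (abs(rep$snr - target_snr) > tol)
    stop_named("sfb_snr_tol", "achieved snr %.4f misses target %.4f by more than tol",
               rep$snr, target_snr)
  list(model = model, spec = spec, snr_report = rep, multiplier = mult)
}

#' Calibrate the exponential censoring rate to a target censoring proportion
#'
#' Bisection on the exponential rate; the censoring proportion at a
#' candidate rate is the Monte Carlo mean of `1(C < T)` (ties `T = C` count
#' as events, matching `delta = 1(T <= C)`). Common uniforms across
#' candidate rates make the objective exactly non-decreasing in the rate.
#'
#' @param model a `response_model`.
#' @param spec an [lp_spec()] (typically already signal-calibrated).
#' @param target desired censoring proportion in (0, 1).
#' @param tol tolerance on the achieved proportion.
#' @param extra_level,n,seed,X covariate draw controls as in [pseudo_r2()].
#' @param max_iter bisection step cap.
#' @return object of class `censoring_calibration` with fields `rate`,
#'   `achieved_proportion`, `target`, `tolerance`.
#' @export
calibrate_censoring_rate <- function(model, spec, target, tol = 0.005,
                                     extra_level = "baseline", n = 1e5,
                                     seed = NULL, X = NULL, max_iter = 60) {
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target >= 1)
    stop_named("sfb_bad_target", "target censoring proportion must lie in (0,1)")
  sd <- derive_seed(seed %||% 0, 11)
  if (is.null(X)) X <- gen_covariates(n, extra_level, seed = sd)
  lp <- linear_predictor(X, spec)
  t <- draw_survival_times(lp, model, x1 = X[, "x1"],
                           seed = derive_seed(sd, 2))
  u <- with_seed(derive_seed(sd, 3), runif(length(t)))
  prop_at <- function(rate) mean(qexp(u, rate) < t)
  lo <- 1e-8; hi <- 1
  it <- 0
  while (prop_at(hi) < target && it < 80) { hi <- hi * 4; it <- it + 1 }
  if (prop_at(hi) < target)
    stop_named("sfb_no_bracket", "could not bracket the target censoring rate")
  rate <- sqrt(lo * hi)
  for (i in seq_len(max_iter)) {
    rate <- sqrt(lo * hi)
    if (abs(prop_at(rate) - target) <= tol * 0.2) break
    if (prop_at(rate) < target) lo <- rate else hi <- rate
  }
  achieved <- prop_at(rate)
  if (abs(achieved - target) > tol)
    stop_named("sfb_cens_tol",
               "achieved censoring %.4f misses target %.4f beyond tol %.4f",
               achieved, target, tol)
  structure(list(rate = rate, achieved_proportion = achieved,
                 target = target, tolerance = tol),
            class = "censoring_calibration")
}

#' @export
print.censoring_calibration <- function(x, ...) {
  cat(sprintf("<censoring_calibration: rate = %.5g, achieved = %.4f (target %.2f)>\n",
              x$rate, x$achieved_proportion, x$target))
  invisible(x)
}
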