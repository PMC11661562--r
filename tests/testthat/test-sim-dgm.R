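test_that("base covariate design has the documented structure and moments", {
  n <- 1e5
  X <- gen_covariates(n, "baseline", seed = 11)
  expect_equal(ncol(X), 10L)
  kinds <- attr(X, "column_kind")
  expect_equal(kinds, c("binary", rep("uniform", 5), rep("categorical5", 4)))
  expect_true(all(X[, "x1"] %in% 0:1))
  expect_true(all(X[, 2:6] >= 0 & X[, 2:6] <= 1))
  expect_true(all(X[, 7:10] %in% 1:5))
  # Bernoulli(0.5) mean within 3 SE
  expect_lt(abs(mean(X[, "x1"]) - 0.5), 3 * sqrt(0.25 / n))
  # uniform mean within 3 SE
  expect_lt(abs(mean(X[, "x3"]) - 0.5), 3 * sqrt(1 / 12 / n))
  # uniform categorical level frequencies
  tab <- table(X[, "x8"]) / n
  expect_true(all(abs(tab - 0.2) < 3 * sqrt(0.2 * 0.8 / n)))
})

test_that("extra-variable levels produce the documented correlation structure", {
  n <- 4e4
  Xc <- gen_covariates(n, "correlated", seed = 12)
  expect_equal(ncol(Xc), 13L)
  for (j in paste0("xc", 1:3)) {
    expect_lt(abs(cor(Xc[, j], Xc[, "x2"]) - 0.75), 0.01)
    expect_lt(abs(mean(Xc[, j])), 3 / sqrt(n))          # mean-zero normal
    expect_lt(abs(sd(Xc[, j]) - 1), 0.02)
  }
  Xn <- gen_covariates(n, "noise", seed = 13)
  expect_equal(ncol(Xn), 60L)
  kinds <- attr(Xn, "column_kind")
  expect_equal(sum(kinds == "extra_noise_corr"), 30L)
  expect_equal(sum(kinds == "extra_noise_indep"), 20L)
  B <- Xn[, kinds == "extra_noise_corr"]
  cm <- cor(B)
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.5), 0.01)
  I <- Xn[, kinds == "extra_noise_indep"]
  ci <- cor(I)
  expect_lt(max(abs(ci[upper.tri(ci)])), 0.03)
  expect_error(gen_covariates(10, "bogus"), class = "sfb_bad_extra_level")
})

test_that("linear predictor is linear in the coefficients and complete per form", {
  X <- gen_covariates(500, "baseline", seed = 21)
  for (form in c("baseline", "poly_int", "sine", "piecewise")) {
    sp <- lp_spec(form)
    lp1 <- linear_predictor(X, sp)
    sp2 <- sp; sp2$signal_scale <- 2
    expect_equal(linear_predictor(X, sp2), 2 * lp1)
    # doubling the scale quadruples the variance, exactly
    expect_equal(var(linear_predictor(X, sp2)), 4 * var(lp1))
    zero <- sp
    zero$coefficients[] <- 0
    expect_equal(linear_predictor(X, zero), rep(0, nrow(X)))
    broken <- sp
    broken$coefficients <- sp$coefficients[-1]
    expect_error(linear_predictor(X, broken), class = "sfb_missing_coef")
  }
  # extra columns carry coefficient zero: lp unchanged by the extra level
  Xc <- gen_covariates(500, "correlated", seed = 21)
  expect_equal(linear_predictor(Xc[, 1:10], lp_spec("baseline")),
               linear_predictor(Xc, lp_spec("baseline")))
})

test_that("piecewise form is continuous at its knots", {
  sp <- lp_spec("piecewise")
  sp$coefficients[] <- 0
  sp$coefficients[paste0("x2_seg", 1:3)] <- c(3, -2, 5)
  X <- gen_covariates(4, "baseline", seed = 3)
  eval_at <- function(x2) {
    X[, "x2"] <- x2
    linear_predictor(X, sp)[1]
  }
  for (k in c(1 / 3, 2 / 3)) {
    expect_equal(eval_at(k - 1e-9), eval_at(k + 1e-9), tolerance = 1e-6)
  }
})

test_that("inverse-cdf survival draws match the family formulas", {
  # exponential special case: rho = 1, lambda = 1, u = 0.5 -> -log(0.5)
  t <- draw_survival_times(0, response_weibull(shape = 1, scale = 1),
                           u = 0.5)
  expect_equal(t, -log(0.5), tolerance = 1e-12)
  # lognormal AFT degenerates to exp(intercept + lp) as sd -> 0
  t2 <- draw_survival_times(0, response_lognormal(intercept = 0, sd = 1e-12),
                            u = 0.37)
  expect_equal(t2, 1, tolerance = 1e-6)
  # weibull survival function of draws matches exp(-lambda t^rho e^lp)
  n <- 2e4
  lp <- 0.7
  m <- response_weibull(shape = 2, scale = 1.5)
  tt <- draw_survival_times(rep(lp, n), m, seed = 31)
  ks <- suppressWarnings(stats::ks.test(
    tt, stats::pweibull, shape = 2,
    scale = (1.5 * exp(lp))^(-1 / 2)))
  expect_gt(ks$p.value, 0.01)
  expect_error(draw_survival_times(c(0, Inf), m), class = "sfb_nonfinite_lp")
})

test_that("generalized gamma with k = 1 reduces to the Weibull distribution", {
  n <- 2e4
  m <- response_gengamma(scale = 1.3, shape = 2.2, k0 = 1, k1 = 1)
  tt <- draw_survival_times(rep(0, n), m, x1 = rep(0:1, n / 2), seed = 41)
  ks <- suppressWarnings(stats::ks.test(tt, stats::pweibull,
                                        shape = 2.2, scale = 1.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("generalized gamma halves have bathtub vs monotone hazards and crossing curves", {
  # the x1 coefficient (1 under the default baseline form) shifts the
  # bathtub half's scale, as in the full mechanism
  n <- 16e4
  x1 <- rep(0:1, each = n / 2)
  m <- response_gengamma()
  tt <- draw_survival_times(1 * x1, m, x1 = x1, seed = 42)
  # average hazard per quantile bin via -log(1 - d/n)/width (robust in
  # wide tail bins, where the bathtub's rising arm lives)
  emp_hazard <- function(t) {
    qs <- unname(stats::quantile(t, c(seq(0, 0.9, length.out = 7), 0.96,
                                      0.99, 0.999)))
    vapply(seq_len(length(qs) - 1), function(i) {
      at_risk <- sum(t >= qs[i])
      ev <- sum(t >= qs[i] & t < qs[i + 1])
      -log(1 - ev / at_risk) / (qs[i + 1] - qs[i])
    }, numeric(1))
  }
  h_bath <- emp_hazard(tt[x1 == 1])   # k = 1/16
  h_mono <- emp_hazard(tt[x1 == 0])   # k = 1 (Weibull, increasing)
  expect_gt(which.min(h_bath), 1)               # dips after the start
  expect_lt(which.min(h_bath), length(h_bath))  # and rises again
  expect_gt(max(h_bath[(which.min(h_bath) + 1):length(h_bath)]),
            1.2 * min(h_bath))
  expect_equal(which.min(h_mono), 1L)           # monotone increasing
  # subgroup survival curves cross at least once
  km0 <- kaplan_meier(tt[x1 == 0], rep(1L, n / 2))
  km1 <- kaplan_meier(tt[x1 == 1], rep(1L, n / 2))
  grid <- sort(unique(c(km0$times, km1$times)))
  dif <- eval_curve(km0, grid) - eval_curve(km1, grid)
  expect_true(any(dif > 0.001) && any(dif < -0.001))
})

test_that("censoring draws are exponential and assembly encodes delta = 1(t <= c)", {
  n <- 1e5
  cc <- draw_censoring(n, rate = 2, seed = 51)
  expect_lt(abs(mean(cc) - 0.5), 3 * 0.5 / sqrt(n))
  expect_gt(draw_censoring(1, 5, seed = 1), 0)
  expect_error(draw_censoring(10, -1), class = "sfb_bad_rate")

  X <- make_uniform_X(2, 2)
  d <- assemble_dataset(c(1, 2), c(2, 1), X)
  expect_equal(d$y, c(1, 1))
  expect_equal(d$delta, c(1L, 0L))
  d2 <- assemble_dataset(c(1, 2), c(Inf, Inf), X)
  expect_equal(d2$delta, c(1L, 1L))
  expect_equal(d2$y, c(1, 2))
  d3 <- assemble_dataset(c(3, 2), c(3, 5), X)  # tie counts as event
  expect_equal(d3$delta[1], 1L)
  expect_error(assemble_dataset(1:3, 1:2, X), class = "sfb_length_mismatch")
  # generated data satisfy the indicator identity exactly
  dd <- make_weibull_data(n = 400, seed = 52, cens_rate = 0.5)
  expect_true(all((dd$delta == 1L) == (dd$t_true == dd$y)))
  expect_true(all(dd$y[dd$delta == 0L] < dd$t_true[dd$delta == 0L]))
})

test_that("dataset CSV round-trip preserves times, status and covariate kinds", {
  d <- make_weibull_data(n = 40, seed = 61)
  f <- tempfile(fileext = ".csv")
  write_surv_dataset(d, f)
  d2 <- read_surv_dataset(f)
  expect_equal(d2$y, d$y)
  expect_equal(d2$delta, d$delta)
  expect_equal(d2$t_true, d$t_true)
  expect_equal(unname(as.matrix(d2$X)), unname(as.matrix(d$X)))
  expect_equal(attr(d2$X, "column_kind"), attr(d$X, "column_kind"))
  unlink(f)
})
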