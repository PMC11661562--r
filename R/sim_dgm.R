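#' Generate the simulation covariate design
#'
#' Draws the 10-covariate base design used by all data-generating mechanisms:
#' `x1 ~ Bernoulli(0.5)`, `x2..x6 ~ Uniform(0,1)` and `x7..x10` five-level
#' categorical variables (default level probabilities 0.2 each). Optionally
#' appends unimportant extra variables:
#'
#' * `"correlated"`: 3 mean-zero unit-variance normal columns, each with
#'   population Pearson correlation 0.75 with a designated important uniform
#'   covariate (default `x2`). The latent Gaussian correlation is set to
#'   `0.75 * sqrt(pi/3)` because `cor(Z, pnorm(Z)) = sqrt(3/pi)` for standard
#'   normal `Z`, which makes the target correlation exact in population.
#' * `"noise"`: 30 standard-normal columns equicorrelated at 0.5 among
#'   themselves (independent of everything else) plus 20 independent
#'   standard-normal columns.
#'
#' @param n number of rows (>= 1).
#' @param extra_level one of `"baseline"`, `"correlated"`, `"noise"`.
#' @param seed optional integer seed (local to this call).
#' @param cat_probs level probabilities for the categorical covariates
#'   (length 5, summing to 1).
#' @param corr_target name of the uniform covariate the correlated extras
#'   track (one of `x2`..`x6`).
#' @return a numeric matrix of class `covariate_matrix` with a
#'   `column_kind` attribute tagging every column.
#' @export
gen_covariates <- function(n, extra_level = c("baseline", "correlated", "noise"),
                           seed = NULL, cat_probs = rep(0.2, 5),
                           corr_target = "x2") {
  if (length(extra_level) != 1L || !extra_level %in% c("baseline", "correlated", "noise"))
    stop_named("sfb_bad_extra_level", "unknown extra_level: %s",
               paste(extra_level, collapse = ","))
  stopifnot(n >= 1, length(cat_probs) == 5, abs(sum(cat_probs) - 1) < 1e-8)
  with_seed(seed, {
    x1 <- rbinom(n, 1L, 0.5)
    U <- matrix(runif(5L * n), n, 5L)
    Cat <- sapply(1:4, function(j) {
      sample.int(5L, n, replace = TRUE, prob = cat_probs)
    })
    X <- cbind(x1, U, Cat)
    colnames(X) <- paste0("x", 1:10)
    kind <- c("binary", rep("uniform", 5L), rep("categorical5", 4L))
    if (extra_level == "correlated") {
      stopifnot(corr_target %in% paste0("x", 2:6))
      r_lat <- 0.75 * sqrt(pi / 3)     # exact population Pearson cor 0.75
      z <- qnorm(X[, corr_target])
      E <- sapply(1:3, function(j) r_lat * z + sqrt(1 - r_lat^2) * rnorm(n))
      colnames(E) <- paste0("xc", 1:3)
      X <- cbind(X, E)
      kind <- c(kind, rep("extra_correlated", 3L))
    } else if (extra_level == "noise") {
      g <- rnorm(n)
      Ec <- sqrt(0.5) * g + sqrt(0.5) * matrix(rnorm(30L * n), n, 30L)
      Ei <- matrix(rnorm(20L * n), n, 20L)
      colnames(Ec) <- paste0("xn", 1:30)
      colnames(Ei) <- paste0("xi", 1:20)
      X <- cbind(X, Ec, Ei)
      kind <- c(kind, rep("extra_noise_corr", 30L), rep("extra_noise_indep", 20L))
    }
    structure(X, column_kind = kind, class = c("covariate_matrix", "matrix", "array"))
  })
}

#' @export
`[.covariate_matrix` <- function(x, i, j, ..., drop = TRUE) {
  k <- attr(x, "column_kind")
  cn <- colnames(x)
  out <- NextMethod()
  if (is.matrix(out)) {
    kk <- if (missing(j)) k
          else if (is.character(j)) k[match(j, cn)]
          else k[j]
    attr(out, "column_kind") <- kk
    class(out) <- c("covariate_matrix", "matrix", "array")
  }
  out
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("<covariate_matrix: %d x %d (%s)>\n", nrow(x), ncol(x),
              paste(unique(attr(x, "column_kind")), collapse = ", ")))
  invisible(x)
}

column_kind <- function(X) attr(X, "column_kind") %||% rep("uniform", ncol(X))

piecewise_knots <- c(1 / 3, 2 / 3)

lp_terms_for_form <- function(form) {
  cat_terms <- as.vector(outer(paste0("x", 7:10), 2:5,
                               function(v, l) paste0(v, "_", l)))
  base_num <- switch(form,
    baseline  = paste0("x", 1:6),
    poly_int  = c("x1", "x2_sq", "x3_x4", "x5_sq", "x2_x5", "x3_x6", "x6"),
    sine      = c("x1", "sin_x2", paste0("x", 3:6)),
    piecewise = c("x1", paste0("x2_seg", 1:3), paste0("x3_seg", 1:3),
                  paste0("x", 4:6)),
    stop_named("sfb_bad_form", "unknown linear-predictor form: %s", form))
  c(base_num, cat_terms)
}

default_lp_coefficients <- function(form) {
  cat_terms <- as.vector(outer(paste0("x", 7:10), 2:5,
                               function(v, l) paste0(v, "_", l)))
  cat_coef <- as.vector(outer(c(1, -1, 0.5, -0.5), c(0.25, 0.5, 0.75, 1)))
  names(cat_coef) <- cat_terms
  num <- switch(form,
    baseline  = c(x1 = 1, x2 = 1, x3 = -1, x4 = 0.8, x5 = -0.8, x6 = 0.6),
    poly_int  = c(x1 = 1, x2_sq = 1, x3_x4 = -1, x5_sq = 0.8, x2_x5 = -0.8,
                  x3_x6 = 0.6, x6 = 0.6),
    sine      = c(x1 = 1, sin_x2 = 1, x3 = -1, x4 = 0.8, x5 = -0.8, x6 = 0.6),
    piecewise = c(x1 = 1, x2_seg1 = 1.5, x2_seg2 = -1.5, x2_seg3 = 1.5,
                  x3_seg1 = -1.2, x3_seg2 = 1.2, x3_seg3 = -1.2,
                  x4 = 0.8, x5 = -0.8, x6 = 0.6))
  c(num, cat_coef)
}

#' Linear-predictor specification
#'
#' Describes how covariates enter the linear predictor `x'beta`. Four forms
#' are supported: `baseline` (all ten covariates first-order, categoricals
#' dummy-coded against level 1), `poly_int` (the `x2, x3, x4, x5` linear
#' terms replaced by `x2^2`, `x3*x4`, `x5^2`, `x2*x5` plus an added `x3*x6`
#' interaction, all among numeric covariates), `sine` (the `x2` term replaced
#' by `sin(2*pi*x2)`) and `piecewise` (`x2` and `x3` piecewise-linear with
#' knots at 1/3 and 2/3, three slopes each, continuous at the knots).
#' Default coefficients ship with the package and can be overridden.
#'
#' @param form one of `"baseline"`, `"poly_int"`, `"sine"`, `"piecewise"`.
#' @param coefficients named numeric vector covering every term of the form;
#'   `NULL` uses the package defaults.
#' @param signal_scale positive multiplier applied to all coefficients
#'   (no intercept lives here; the AFT intercept sits in the response model).
#' @export
lp_spec <- function(form = c("baseline", "poly_int", "sine", "piecewise"),
                    coefficients = NULL, signal_scale = 1) {
  form <- match.arg(form)
  stopifnot(signal_scale >= 0)
  coefficients <- coefficients %||% default_lp_coefficients(form)
  structure(list(form = form, coefficients = coefficients,
                 signal_scale = signal_scale),
            class = "lp_spec")
}

pw_segments <- function(x, knots = piecewise_knots) {
  cbind(pmin(x, knots[1]),
        pmax(0, pmin(x, knots[2]) - knots[1]),
        pmax(0, x - knots[2]))
}

#' Evaluate a linear predictor
#'
#' Computes `signal_scale * sum(term * coefficient)` row-wise. Categorical
#' covariates are dummy-coded with level 1 as reference; extra (unimportant)
#' columns receive coefficient zero by construction.
#'
#' @param X a `covariate_matrix` (must contain the base columns `x1..x10`).
#' @param spec an [lp_spec()].
#' @return numeric vector of length `nrow(X)`.
#' @export
linear_predictor <- function(X, spec) {
  stopifnot(inherits(spec, "lp_spec"))
  if (!all(paste0("x", 1:10) %in% colnames(X)))
    stop_named("sfb_bad_design", "X must contain the base columns x1..x10")
  need <- lp_terms_for_form(spec$form)
  miss <- setdiff(need, names(spec$coefficients))
  if (length(miss))
    stop_named("sfb_missing_coef", "missing coefficient(s): %s",
               paste(miss, collapse = ", "))
  n <- nrow(X)
  Terms <- matrix(0, n, length(need), dimnames = list(NULL, need))
  for (v in paste0("x", 1:6)) if (v %in% need) Terms[, v] <- X[, v]
  if ("sin_x2" %in% need) Terms[, "sin_x2"] <- sin(2 * pi * X[, "x2"])
  if ("x2_sq" %in% need) {
    Terms[, "x2_sq"] <- X[, "x2"]^2
    Terms[, "x3_x4"] <- X[, "x3"] * X[, "x4"]
    Terms[, "x5_sq"] <- X[, "x5"]^2
    Terms[, "x2_x5"] <- X[, "x2"] * X[, "x5"]
    Terms[, "x3_x6"] <- X[, "x3"] * X[, "x6"]
  }
  if ("x2_seg1" %in% need) {
    Terms[, paste0("x2_seg", 1:3)] <- pw_segments(X[, "x2"])
    Terms[, paste0("x3_seg", 1:3)] <- pw_segments(X[, "x3"])
  }
  for (v in paste0("x", 7:10)) {
    for (l in 2:5) Terms[, paste0(v, "_", l)] <- as.numeric(X[, v] == l)
  }
  drop(Terms %*% spec$coefficients[need]) * spec$signal_scale
}

#' Response-family models
#'
#' Three conditional distributions for the survival time given the linear
#' predictor `lp`:
#'
#' * `response_weibull(shape, scale)`: proportional hazards,
#'   `h(t|x) = scale * shape * t^(shape-1) * exp(lp)`; draws use
#'   `t = (-log(u) / (scale * exp(lp)))^(1/shape)`.
#' * `response_lognormal(intercept, sd)`: accelerated failure time,
#'   `log(t) = intercept + lp + sd * z` with standard-normal `z`.
#' * `response_gengamma(scale, shape, k0, k1)`: generalized gamma with
#'   density `b * t^(b*k-1) * exp(-(t/a')^b) / (a'^(b*k) * gamma(k))`,
#'   `a' = scale * exp(lp)`, `b = shape`; the shape `k` is `k0` where
#'   `x1 = 0` and `k1` where `x1 = 1`. The default `k1 = 1/16` produces a
#'   bathtub-shaped hazard in that half of the sample whose survival and
#'   hazard curves cross those of the monotone `k0 = 1` (Weibull) half.
#'   `GG(a, b, 1)` coincides with `Weibull(a, b)`.
#'
#' @param shape,scale,intercept,sd,k0,k1 family parameters (all scale/shape
#'   parameters strictly positive).
#' @return an object of class `response_model`.
#' @export
response_weibull <- function(shape = 2, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  structure(list(family = "weibull_ph", shape = shape, scale = scale),
            class = "response_model")
}

#' @rdname response_weibull
#' @export
response_lognormal <- function(intercept = 0, sd = 0.5) {
  stopifnot(sd > 0)
  structure(list(family = "lognormal_aft", intercept = intercept, sd = sd),
            class = "response_model")
}

#' @rdname response_weibull
#' @export
response_gengamma <- function(scale = 1, shape = 2, k0 = 1, k1 = 1 / 16) {
  stopifnot(scale > 0, shape > 0, k0 > 0, k1 > 0)
  structure(list(family = "gen_gamma", scale = scale, shape = shape,
                 k0 = k0, k1 = k1),
            class = "response_model")
}

response_model_for <- function(dgm_y) {
  switch(dgm_y,
         weibull = response_weibull(),
         aft     = response_lognormal(),
         gg      = response_gengamma(),
         stop_named("sfb_bad_dgm", "unknown dgm_y: %s", dgm_y))
}

#' Draw survival times by inverse-cdf sampling
#'
#' @param lp linear predictor vector (finite).
#' @param model a `response_model`.
#' @param x1 binary vector (required for the generalized gamma family, which
#'   switches its `k` shape on `x1`).
#' @param seed optional integer seed (local).
#' @param u optional vector of uniforms (testing hook); drawn if `NULL`.
#' @return strictly positive time vector.
#' @export
draw_survival_times <- function(lp, model, x1 = NULL, seed = NULL, u = NULL) {
  stopifnot(inherits(model, "response_model"))
  if (any(!is.finite(lp)))
    stop_named("sfb_nonfinite_lp", "linear predictor contains non-finite entries")
  n <- length(lp)
  with_seed(seed, {
    if (is.null(u)) u <- runif(n)
    stopifnot(length(u) == n)
    t <- switch(model$family,
      weibull_ph = (-log(u) / (model$scale * exp(lp)))^(1 / model$shape),
      lognormal_aft = exp(model$intercept + lp + model$sd * qnorm(u)),
      gen_gamma = {
        if (is.null(x1)) stop_named("sfb_missing_x1",
                                    "x1 is required for the gen_gamma family")
        stopifnot(length(x1) == n, all(x1 %in% c(0, 1)))
        k <- ifelse(x1 == 1, model$k1, model$k0)
        (model$scale * exp(lp)) * qgamma(u, shape = k)^(1 / model$shape)
      })
    pmax(t, .Machine$double.xmin)
  })
}

#' Draw i.i.d. exponential censoring times
#'
#' @param n number of draws.
#' @param rate exponential rate (> 0).
#' @param seed optional integer seed (local).
#' @export
draw_censoring <- function(n, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_named("sfb_bad_rate", "censoring rate must be a single positive number")
  with_seed(seed, rexp(n, rate))
}

#' Assemble an observed dataset from latent times
#'
#' Applies right censoring: `y = min(t, c)` and `delta = 1(t <= c)` (ties
#' count as events). The latent times are retained for simulation metrics.
#'
#' @param t latent survival times.
#' @param c censoring times (may be `Inf`).
#' @param X a `covariate_matrix` with `length(t)` rows.
#' @return object of class `surv_dataset` with fields `y`, `delta`,
#'   `t_true`, `X`.
#' @export
assemble_dataset <- function(t, c, X) {
  if (length(t) != length(c) || length(t) != nrow(X))
    stop_named("sfb_length_mismatch",
               "t (%d), c (%d) and rows of X (%d) must agree",
               length(t), length(c), nrow(X))
  surv_dataset(y = pmin(t, c), delta = as.integer(t <= c), X = X, t_true = t)
}

#' Construct a survival dataset
#'
#' @param y observed times (> 0).
#' @param delta event indicators in `{0,1}`.
#' @param X covariate matrix.
#' @param t_true optional latent survival times (simulated data).
#' @export
surv_dataset <- function(y, delta, X, t_true = NULL) {
  stopifnot(length(y) == length(delta), length(y) == nrow(X),
            all(y > 0), all(delta %in% c(0L, 1L)))
  if (!is.null(t_true)) stopifnot(length(t_true) == length(y))
  structure(list(y = as.numeric(y), delta = as.integer(delta),
                 t_true = t_true, X = X),
            class = "surv_dataset")
}

#' @export
print.surv_dataset <- function(x, ...) {
  cat(sprintf("<surv_dataset: n = %d, events = %d (%.1f%%), p = %d%s>\n",
              length(x$y), sum(x$delta), 100 * mean(x$delta), ncol(x$X),
              if (is.null(x$t_true)) "" else ", latent times retained"))
  invisible(x)
}

#' Write / read a survival dataset as a delimited table
#'
#' Column layout: `time`, `status`, optionally `t_true`, then covariates.
#' @param data a `surv_dataset`.
#' @param file path to write.
#' @export
write_surv_dataset <- function(data, file) {
  df <- data.frame(time = data$y, status = data$delta)
  if (!is.null(data$t_true)) df$t_true <- data$t_true
  df <- cbind(df, as.data.frame(unclass(data$X)))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_surv_dataset
#' @param kinds optional `column_kind` tags for the covariate columns;
#'   guessed (integer 1..5 columns as categorical) when omitted.
#' @export
read_surv_dataset <- function(file, kinds = NULL) {
  df <- utils::read.csv(file)
  stopifnot(all(c("time", "status") %in% names(df)))
  t_true <- if ("t_true" %in% names(df)) df$t_true else NULL
  xcols <- setdiff(names(df), c("time", "status", "t_true"))
  X <- as.matrix(df[xcols])
  if (is.null(kinds)) {
    kinds <- vapply(xcols, function(v) {
      x <- X[, v]
      if (all(x %in% 0:1)) "binary"
      else if (all(x == round(x)) && all(x %in% 1:5)) "categorical5"
      else "uniform"
    }, character(1))
  }
  attr(X, "column_kind") <- unname(kinds)
  class(X) <- c("covariate_matrix", "matrix", "array")
  surv_dataset(df$time, df$status, X, t_true)
}
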