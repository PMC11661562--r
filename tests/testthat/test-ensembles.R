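test_that("imputation leaves uncensored data untouched and RIST reduces to its first ensemble", {
  d <- make_weibull_data(n = 60, seed = 201, cens_rate = 1e-9)
  expect_true(all(d$delta == 1L))
  spec <- forest_spec("rist", n_trees = 5, seed = 21)
  f <- fit_rist(d, spec)
  f0 <- survforestbench:::fit_forest_base(d, spec, ert = TRUE,
                                          rows_override = seq_along(d$y))
  Xq <- gen_covariates(8, "baseline", seed = 202)
  expect_identical(predict_survival(f, Xq), predict_survival(f0, Xq))
  imp <- impute_censored(d, f, seed = 23)
  expect_identical(imp$y, d$y)
})

test_that("imputed times strictly exceed censoring times and events are preserved", {
  d <- make_weibull_data(n = 100, seed = 203, cens_rate = 1)
  expect_true(any(d$delta == 0L))
  f <- survforestbench:::fit_forest_base(d, forest_spec("rist", n_trees = 10,
                                                        seed = 25),
                                         ert = TRUE,
                                         rows_override = seq_along(d$y))
  imp <- impute_censored(d, f, seed = 27)
  cens <- d$delta == 0L
  expect_true(all(imp$y[cens] > d$y[cens]))
  expect_identical(imp$y[!cens], d$y[!cens])
  expect_true(all(imp$delta == 1L))
  # replay determinism of the imputation draw
  imp2 <- impute_censored(d, f, seed = 27)
  expect_identical(imp, imp2)
})

test_that("a degenerate one-point conditional distribution imputes that point", {
  # all events at a single time beyond every censoring time: the ensemble
  # curve has a single grid point, which every imputation must return
  n <- 30
  X <- make_uniform_X(n, 2, seed = 41)
  y <- c(rep(0.5, 10), rep(3, 20))
  delta <- c(rep(0L, 10), rep(1L, 20))
  d <- surv_dataset(y, delta, X)
  f <- fit_rsf(d, forest_spec("rsf_logrank", n_trees = 3, min_node = 30,
                              seed = 29, bootstrap = FALSE))
  imp <- impute_censored(d, f, seed = 31)
  expect_true(all(imp$y[1:10] == 3))
})

test_that("rotation blocks are orthogonal and subset size one matches plain RSF", {
  d <- make_weibull_data(n = 80, seed = 204, cens_rate = 0.3)
  f <- fit_rotsf(d, forest_spec("rotsf", n_trees = 3, seed = 33))
  for (Q in f$rotations) {
    expect_equal(crossprod(Q), diag(ncol(Q)), tolerance = 1e-10)
  }
  # purely numeric design, subset size 1: rotations are axis reflections,
  # so trees and predictions coincide with plain RSF on the same streams
  n <- 90
  X <- make_uniform_X(n, 4, seed = 42)
  t <- with_seed_local(43, rexp(n, exp(X[, 1] - X[, 2])))
  dd <- assemble_dataset(t, draw_censoring(n, 0.2, seed = 44), X)
  s_rot <- forest_spec("rotsf", n_trees = 4, mtry = 2, rot_subset_size = 1,
                       seed = 35)
  s_rsf <- forest_spec("rsf_logrank", n_trees = 4, mtry = 2, seed = 35)
  Xq <- make_uniform_X(10, 4, seed = 45)
  p_rot <- predict_survival(fit_rotsf(dd, s_rot), Xq)
  p_rsf <- predict_survival(fit_rsf(dd, s_rsf), Xq)
  expect_equal(p_rot, p_rsf, tolerance = 1e-10)
})

test_that("CIF stops at pure-noise roots at about the nominal rate", {
  nrep <- 150
  stumps <- vapply(seq_len(nrep), function(r) {
    n <- 60
    X <- make_uniform_X(n, 4, seed = 500 + r)
    y <- with_seed_local(700 + r, rexp(n))
    d <- surv_dataset(y, rep(1L, n), X)
    f <- fit_cif(d, forest_spec("cif", n_trees = 1, mtry = 4, seed = 900 + r))
    length(f$trees[[1]]$nodes) == 1L
  }, logical(1))
  rate <- mean(stumps)
  # Bonferroni keeps the family-wise split probability at or below ~alpha
  expect_gt(rate, 0.88)
  expect_lte(rate, 1)
})

test_that("CIF splits on a strongly prognostic covariate and its weights sum to one", {
  d <- make_separable_data(n = 80, seed = 6)
  f <- fit_cif(d, forest_spec("cif", n_trees = 5, mtry = 2, min_node = 5,
                              seed = 37))
  roots <- vapply(f$trees, function(tr) {
    nd <- tr$nodes[[tr$root]]
    if (nd$leaf) NA_integer_ else nd$var
  }, integer(1))
  expect_true(all(roots == 1L, na.rm = TRUE))
  expect_true(sum(!is.na(roots)) >= 4)
  # nearest-neighbour weight normalization: weighted KM starts at 1 and the
  # per-query weights sum to one by construction
  Xq <- d$X[1:6, ]
  cvs <- predict_survival(f, Xq)
  for (cv in cvs) expect_lte(cv$values[1], 1)
  # direct check of the weight matrix
  Xm <- survforestbench:::encode_raw(Xq)$Xm
  W <- matrix(0, nrow(Xm), length(f$train$y))
  for (b in seq_along(f$trees)) {
    tr <- f$trees[[b]]
    ids <- survforestbench:::route_tree(tr, Xm)
    for (id in unique(ids)) {
      rows <- tr$nodes[[id]]$rows
      qs <- which(ids == id)
      W[qs, rows] <- W[qs, rows] + 1 / length(rows)
    }
  }
  W <- W / rowSums(W)
  expect_equal(rowSums(W), rep(1, nrow(Xm)))
})

test_that("forest predictions beat a covariate-free Kaplan-Meier median on strong signal", {
  # parameter-recovery sanity floor at desk scale
  cal <- calibrate_flc(list(dgm_y = "weibull", dgm_x = "baseline",
                            censoring = 0.10),
                       n = 1e4, seed = 51)
  flc <- list(dgm_y = "weibull", dgm_x = "baseline", censoring = 0.10,
              extra = "baseline")
  train <- simulate_flc_dataset(flc, 300, cal, seed = 61)
  test <- simulate_flc_dataset(flc, 150, cal, seed = 62)
  km_med <- predict_median(kaplan_meier(train$y, train$delta))
  base_L <- absolute_loss(test$t_true, rep(km_med, 150))
  for (meth in c("rsf_logrank", "rist", "rotsf", "cif")) {
    f <- fit_forest(train, forest_spec(meth, n_trees = 40, seed = 63))
    L <- absolute_loss(test$t_true, predict_medians(f, test$X))
    expect_lt(L, base_L)
  }
})
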