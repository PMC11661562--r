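test_that("a node constraint at or above n yields a stump with the pooled hazard", {
  d <- make_weibull_data(n = 50, seed = 101)
  spec <- forest_spec("rsf_logrank", n_trees = 1, min_node = 50, seed = 1)
  tr <- grow_tree(d, spec, seed = 1)
  expect_length(tr$tree$nodes, 1L)
  expect_true(tr$tree$nodes[[1]]$leaf)
  na <- nelson_aalen(d$y, d$delta)
  expect_equal(tr$tree$nodes[[1]]$H, eval_curve(na, tr$grid))
})

test_that("a perfectly separating covariate is recovered at the root", {
  d <- make_separable_data(n = 60, seed = 2)
  spec <- forest_spec("rsf_logrank", n_trees = 1, mtry = 2, min_node = 5,
                      seed = 3)
  tr <- grow_tree(d, spec, seed = 3)
  root <- tr$tree$nodes[[tr$tree$root]]
  expect_false(root$leaf)
  expect_equal(root$var, 1L)
  # oracle: exhaustive enumeration of all splits of both covariates
  best <- -Inf; best_v <- NA
  for (v in 1:2) {
    x <- d$X[, v]
    for (cc in sort(unique(x))[-1]) {
      s <- split_statistic(d$y, d$delta, x < cc, "logrank")
      if (s > best) { best <- s; best_v <- v }
    }
  }
  expect_equal(root$var, best_v)
})

test_that("tree growth on full candidate sets is deterministic on replay", {
  d <- make_weibull_data(n = 80, seed = 103, cens_rate = 0.4)
  spec <- forest_spec("rsf_logrank", n_trees = 1, mtry = 10, seed = 5)
  t1 <- grow_tree(d, spec, seed = 5)
  t2 <- grow_tree(d, spec, seed = 5)
  expect_identical(t1, t2)
  expect_error(grow_tree(surv_dataset(c(1, 2), c(0L, 0L),
                                      make_uniform_X(2, 2)), spec),
               class = "sfb_no_events")
})

test_that("forests replay bit-identically and honour the B=1 single-tree contract", {
  d <- make_weibull_data(n = 70, seed = 104, cens_rate = 0.3)
  Xq <- gen_covariates(12, "baseline", seed = 105)
  for (meth in c("rsf_logrank", "rist", "rotsf", "cif")) {
    spec <- forest_spec(meth, n_trees = 4, seed = 9)
    f1 <- fit_forest(d, spec)
    f2 <- fit_forest(d, spec)
    expect_identical(predict_survival(f1, Xq), predict_survival(f2, Xq))
  }
  # with bootstrap disabled and full mtry, an ensemble of identical trees
  # equals the single tree
  sp1 <- forest_spec("rsf_logrank", n_trees = 3, mtry = 10, seed = 2,
                     bootstrap = FALSE)
  sp2 <- forest_spec("rsf_logrank", n_trees = 1, mtry = 10, seed = 7,
                     bootstrap = FALSE)
  p3 <- predict_survival(fit_rsf(d, sp1), Xq)
  p1 <- predict_survival(fit_rsf(d, sp2), Xq)
  expect_equal(p3, p1, tolerance = 1e-12)
})

test_that("every terminal node keeps at least one unique event time", {
  d <- make_weibull_data(n = 100, seed = 106, cens_rate = 0.8)
  for (meth in c("rsf_logrank", "rsf_logrank_score", "rist", "cif")) {
    f <- fit_forest(d, forest_spec(meth, n_trees = 5, seed = 11))
    if (meth == "cif") {
      counts <- unlist(lapply(f$trees, function(tr)
        vapply(Filter(function(nd) nd$leaf, tr$nodes), function(nd) {
          rows <- nd$rows
          length(unique(d$y[rows][d$delta[rows] == 1L]))
        }, numeric(1))))
    } else {
      counts <- survforestbench:::leaf_event_counts(f)
    }
    expect_true(all(counts >= 1))
  }
})

test_that("ensemble survival curves are monotone, in (0,1], and grid-aligned", {
  d <- make_weibull_data(n = 80, seed = 107, cens_rate = 0.4)
  Xq <- gen_covariates(10, "baseline", seed = 108)
  for (meth in c("rsf_logrank", "rist", "rotsf", "cif")) {
    f <- fit_forest(d, forest_spec(meth, n_trees = 6, seed = 13))
    for (cv in predict_survival(f, Xq)) {
      expect_s3_class(cv, "survival_curve")
      expect_equal(cv$times, f$grid)
      expect_true(all(diff(cv$values) <= 1e-12))
      if (meth == "cif") {
        # weighted Kaplan-Meier may legitimately reach zero
        expect_true(all(cv$values >= 0 & cv$values <= 1))
      } else {
        # exp(-mean CHF) stays strictly positive
        expect_true(all(cv$values > 0 & cv$values <= 1))
      }
    }
  }
})

test_that("out-of-bag sets are disjoint from the bootstrap multisets", {
  d <- make_weibull_data(n = 60, seed = 109)
  f <- fit_rsf(d, forest_spec("rsf_logrank", n_trees = 5, seed = 15))
  for (b in 1:5) {
    oob <- survforestbench:::oob_rows(f, b)
    expect_length(intersect(oob, f$inbag[[b]]), 0L)
    expect_true(length(oob) > 0)
  }
})

test_that("unseen categorical levels are routed by the majority direction", {
  n <- 80
  X <- with_seed_local(31, cbind(g = sample(c(1, 2, 4, 5), n, replace = TRUE),
                                 z = runif(n)))
  attr(X, "column_kind") <- c("categorical5", "uniform")
  class(X) <- c("covariate_matrix", "matrix", "array")
  y <- with_seed_local(32, ifelse(X[, "g"] <= 2, runif(n, 1, 2), runif(n, 4, 5)))
  d <- surv_dataset(y, rep(1L, n), X)
  f <- fit_rsf(d, forest_spec("rsf_logrank", n_trees = 3, mtry = 2, seed = 17))
  Xq <- X[1:2, ]
  Xq[, "g"] <- c(3, 3)   # level never seen in training
  cv <- predict_survival(f, Xq)
  expect_true(all(is.finite(cv[[1]]$values)))
})

test_that("mean CHF to survival mapping keeps zero hazard at one", {
  # single stump tree: every query returns the root curve
  d <- make_weibull_data(n = 40, seed = 110)
  f <- fit_rsf(d, forest_spec("rsf_logrank", n_trees = 1, min_node = 40,
                              seed = 19, bootstrap = FALSE))
  cvs <- predict_survival(f, gen_covariates(5, "baseline", seed = 111))
  for (i in 2:5) expect_equal(cvs[[i]], cvs[[1]])
  na <- nelson_aalen(d$y, d$delta)
  expect_equal(cvs[[1]]$values, exp(-eval_curve(na, f$grid)))
})
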