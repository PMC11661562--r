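#' Forest specification
#'
#' Hyperparameters shared by the forest construction methods.
#'
#' @param method one of `"rsf_logrank"`, `"rsf_logrank_score"`,
#'   `"rsf_cindex"`, `"rsf_brier"`, `"rsf_l1"`, `"rist"`, `"rotsf"`,
#'   `"cif"`.
#' @param n_trees ensemble size `B`.
#' @param mtry candidate covariates per node `M` (default `ceiling(sqrt(p))`,
#'   resolved at fit time).
#' @param min_node minimum rows in a child node.
#' @param min_events minimum unique event times per terminal node.
#' @param rist_folds number of imputation rounds `k >= 1` (RIST only).
#' @param cif_alpha stopping level for the conditional-inference association
#'   test (after Bonferroni over the candidates).
#' @param cif_perms permutation count for the association test; `0` uses the
#'   asymptotic reference distribution (fast mode, the default).
#' @param rot_subset_size size of the rotated column subsets (RotSF only).
#' @param seed integer seed; every tree derives its own bootstrap, rotation
#'   and growth substreams from it, so fits replay identically regardless of
#'   scheduling.
#' @param bootstrap draw bootstrap samples (`FALSE` is a testing hook that
#'   grows every tree on the full sample).
#' @export
forest_spec <- function(method = c("rsf_logrank", "rsf_logrank_score",
                                   "rsf_cindex", "rsf_brier", "rsf_l1",
                                   "rist", "rotsf", "cif"),
                        n_trees = 500L, mtry = NULL, min_node = 6L,
                        min_events = 1L, rist_folds = 1L, cif_alpha = 0.05,
                        cif_perms = 0L, rot_subset_size = 3L, seed = 1L,
                        bootstrap = TRUE) {
  method <- match.arg(method)
  stopifnot(n_trees >= 1, min_node >= 1, min_events >= 1, rist_folds >= 1,
            cif_alpha > 0, cif_alpha < 1, rot_subset_size >= 1)
  structure(list(method = method, n_trees = as.integer(n_trees), mtry = mtry,
                 min_node = as.integer(min_node),
                 min_events = as.integer(min_events),
                 rist_folds = as.integer(rist_folds), cif_alpha = cif_alpha,
                 cif_perms = as.integer(cif_perms),
                 rot_subset_size = as.integer(rot_subset_size),
                 seed = as.integer(seed), bootstrap = bootstrap),
            class = "forest_spec")
}

criterion_for <- function(method) {
  switch(method,
         rsf_logrank = "logrank", rsf_logrank_score = "logrank_score",
         rsf_cindex = "cindex", rsf_brier = "brier", rsf_l1 = "l1",
         rist = "logrank", rotsf = "logrank", cif = "logrank_score")
}

encode_raw <- function(X) {
  kinds <- column_kind(X)
  Xm <- unclass(X)
  class(Xm) <- NULL
  Xm <- matrix(as.numeric(Xm), nrow(X), ncol(X),
               dimnames = list(NULL, colnames(X)))
  list(Xm = Xm, is_cat = kinds == "categorical5")
}

encode_onehot <- function(X) {
  kinds <- column_kind(X)
  cols <- list(); nms <- character(0)
  for (j in seq_len(ncol(X))) {
    if (kinds[j] == "categorical5") {
      for (l in 2:5) {
        cols[[length(cols) + 1L]] <- as.numeric(X[, j] == l)
        nms <- c(nms, paste0(colnames(X)[j], "_", l))
      }
    } else {
      cols[[length(cols) + 1L]] <- as.numeric(X[, j])
      nms <- c(nms, colnames(X)[j])
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

# --- tree growth -----------------------------------------------------------

leaf_curve_on_grid <- function(y, delta, grid) {
  rt <- risk_table(y, delta)
  H <- cumsum(rt$d / rt$n_risk)
  idx <- findInterval(grid, rt$times)
  list(H = ifelse(idx == 0L, 0, H[pmax(idx, 1L)]),
       n_unique_events = length(rt$times))
}

cif_node_test <- function(y, delta, x, is_cat, a, perms) {
  m <- length(y)
  abar <- mean(a)
  ssa <- sum((a - abar)^2)
  if (ssa <= 0) return(1)
  if (!is_cat) {
    obs_stat <- function(av) {
      Tl <- sum(x * av)
      v <- sum((x - mean(x))^2) * sum((av - mean(av))^2) / (m - 1)
      if (v <= 0) return(0)
      abs(Tl - sum(x) * mean(av)) / sqrt(v)
    }
    z <- obs_stat(a)
    if (perms > 0) {
      exc <- sum(vapply(seq_len(perms),
                        function(i) obs_stat(sample(a)) >= z, logical(1)))
      (1 + exc) / (perms + 1)
    } else 2 * pnorm(-z)
  } else {
    lev <- sort(unique(x))
    if (length(lev) < 2L) return(1)
    kstat <- function(av) {
      ab <- mean(av)
      ss <- sum((av - ab)^2)
      if (ss <= 0) return(0)
      s <- vapply(lev, function(l) sum(av[x == l]), numeric(1))
      nl <- vapply(lev, function(l) sum(x == l), numeric(1))
      (m - 1) / ss * sum((s - nl * ab)^2 / nl)
    }
    st <- kstat(a)
    if (perms > 0) {
      exc <- sum(vapply(seq_len(perms),
                        function(i) kstat(sample(a)) >= st, logical(1)))
      (1 + exc) / (perms + 1)
    } else pchisq(st, df = length(lev) - 1, lower.tail = FALSE)
  }
}

# Grow one survival tree on rows of (y, delta, Xm). Returns a list of node
# records; terminal nodes carry either the Nelson-Aalen curve on `grid` or
# (for nearest-neighbour aggregation) the row indices they contain.
grow_tree_impl <- function(y, delta, Xm, is_cat, grid, criterion, mtry,
                           min_node, min_events, ert = FALSE, cif = NULL,
                           store_rows = FALSE, row_ids = NULL) {
  p <- ncol(Xm)
  nodes <- list()
  new_id <- function() length(nodes) + 1L

  make_leaf <- function(rows) {
    id <- new_id()
    lc <- leaf_curve_on_grid(y[rows], delta[rows], grid)
    nodes[[id]] <<- list(leaf = TRUE, H = lc$H,
                         n = length(rows),
                         n_unique_events = lc$n_unique_events,
                         rows = if (store_rows) row_ids[rows])
    id
  }

  # best cut of one candidate covariate; categorical levels are ordered by
  # their within-node Kaplan-Meier medians and then treated as ordinal
  score_var <- function(rows, v) {
    x <- Xm[rows, v]
    lev <- NULL; ord <- NULL; xr <- x
    if (is_cat[v]) {
      lev <- sort(unique(x))
      if (length(lev) < 2L) return(NULL)
      med <- vapply(lev, function(l) {
        m <- x == l
        km_median_quick(y[rows][m], delta[rows][m])
      }, numeric(1))
      ord <- lev[order(med, lev)]
      xr <- match(x, ord)
    } else if (length(unique(x)) < 2L) return(NULL)
    cuts <- NULL
    if (ert) cuts <- runif(1, min(xr), max(xr))
    bc <- best_cut_numeric(y[rows], delta[rows], xr, criterion,
                           min_node, min_events, cuts = cuts)
    if (is.null(bc)) return(NULL)
    if (!is.null(lev)) {
      bc$left_levels <- ord[seq_len(floor(bc$cut))]
      bc$seen_levels <- lev
    }
    bc
  }

  build <- function(rows) {
    m <- length(rows)
    if (m < 2L * min_node) return(make_leaf(rows))
    cand <- sort(sample.int(p, min(mtry, p)))
    if (!is.null(cif)) {
      a <- logrank_scores(y[rows], delta[rows])
      pv <- vapply(cand, function(v)
        cif_node_test(y[rows], delta[rows], Xm[rows, v], is_cat[v], a,
                      cif$perms), numeric(1))
      padj <- pmin(1, pv * length(cand))
      if (min(padj) > cif$alpha) return(make_leaf(rows))
      cand <- cand[order(pv, cand)][1L]
    }
    best <- NULL; best_v <- NA_integer_
    for (v in cand) {
      bc <- score_var(rows, v)
      if (!is.null(bc) && (is.null(best) || bc$score > best$score)) {
        best <- bc; best_v <- v
      }
    }
    if (is.null(best)) return(make_leaf(rows))
    x <- Xm[rows, best_v]
    left <- if (is_cat[best_v]) x %in% best$left_levels else x <= best$cut
    lid <- build(rows[left])
    rid <- build(rows[!left])
    id <- new_id()
    nodes[[id]] <<- list(leaf = FALSE, var = best_v, cut = best$cut,
                         left_levels = best$left_levels,
                         seen_levels = best$seen_levels,
                         maj_left = sum(left) >= sum(!left),
                         left = lid, right = rid)
    id
  }

  if (is.null(row_ids)) row_ids <- seq_along(y)
  root <- build(seq_along(y))
  list(nodes = nodes, root = root)
}

# Drop query rows down a tree; returns the terminal node id for each row.
route_tree <- function(tree, Xm) {
  n <- nrow(Xm)
  at <- rep(tree$root, n)
  repeat {
    open <- which(!vapply(tree$nodes[at], `[[`, logical(1), "leaf"))
    if (!length(open)) break
    for (id in unique(at[open])) {
      nd <- tree$nodes[[id]]
      rows <- which(at == id)
      x <- Xm[rows, nd$var]
      if (!is.null(nd$left_levels)) {
        left <- x %in% nd$left_levels
        unseen <- !(x %in% nd$seen_levels)
        left[unseen] <- nd$maj_left
      } else left <- x <= nd$cut
      at[rows[left]] <- nd$left
      at[rows[!left]] <- nd$right
    }
  }
  at
}

#' Grow a single survival tree
#'
#' Recursive best-split search over `mtry` sampled candidate covariates;
#' numeric covariates are scanned over all midpoints between sorted unique
#' values, categorical covariates over cutpoints of their within-node
#' Kaplan-Meier-median level ordering. A node becomes terminal when no valid
#' split exists (child size below `min_node` or a child without
#' `min_events` unique event times). Terminal nodes store the Nelson-Aalen
#' cumulative hazard of their rows on the training event-time grid.
#'
#' @param data a `surv_dataset` with at least one event.
#' @param spec a [forest_spec()]; its criterion, `mtry` and node constraints
#'   are used.
#' @param seed optional integer seed (local).
#' @return object of class `survival_tree`.
#' @export
grow_tree <- function(data, spec, seed = NULL) {
  stopifnot(inherits(data, "surv_dataset"), inherits(spec, "forest_spec"))
  if (!any(data$delta == 1L))
    stop_named("sfb_no_events", "cannot grow a tree on data without events")
  enc <- encode_raw(data$X)
  grid <- sort(unique(data$y[data$delta == 1L]))
  mtry <- spec$mtry %||% ceiling(sqrt(ncol(enc$Xm)))
  tree <- with_seed(seed, grow_tree_impl(
    data$y, data$delta, enc$Xm, enc$is_cat, grid,
    criterion_for(spec$method), mtry, spec$min_node, spec$min_events,
    ert = spec$method == "rist",
    cif = if (spec$method == "cif") list(alpha = spec$cif_alpha,
                                         perms = spec$cif_perms)))
  structure(list(tree = tree, grid = grid, is_cat = enc$is_cat,
                 method = spec$method), class = "survival_tree")
}

# --- forest fitting --------------------------------------------------------

draw_rows_with_events <- function(n, delta, seed, replace, size = n) {
  with_seed(seed, {
    repeat {
      rows <- sample.int(n, size, replace = replace)
      if (any(delta[rows] == 1L)) return(rows)
    }
  })
}

fit_forest_base <- function(data, spec, ert = FALSE, cif = FALSE,
                            subsample_frac = NULL, rows_override = NULL,
                            grid = NULL) {
  stopifnot(inherits(data, "surv_dataset"), inherits(spec, "forest_spec"))
  if (!any(data$delta == 1L))
    stop_named("sfb_no_events", "training data contains no events")
  enc <- encode_raw(data$X)
  n <- length(data$y)
  grid <- grid %||% sort(unique(data$y[data$delta == 1L]))
  mtry <- spec$mtry %||% ceiling(sqrt(ncol(enc$Xm)))
  crit <- criterion_for(spec$method)
  trees <- vector("list", spec$n_trees)
  inbag <- vector("list", spec$n_trees)
  for (b in seq_len(spec$n_trees)) {
    rows <- if (!is.null(rows_override)) rows_override
      else if (!is.null(subsample_frac))
        draw_rows_with_events(n, data$delta, derive_seed(spec$seed, b, 1),
                              replace = FALSE, size = floor(subsample_frac * n))
      else if (spec$bootstrap)
        draw_rows_with_events(n, data$delta, derive_seed(spec$seed, b, 1),
                              replace = TRUE)
      else seq_len(n)
    trees[[b]] <- with_seed(derive_seed(spec$seed, b, 2), grow_tree_impl(
      data$y[rows], data$delta[rows], enc$Xm[rows, , drop = FALSE],
      enc$is_cat, grid, crit, mtry, spec$min_node, spec$min_events,
      ert = ert,
      cif = if (cif) list(alpha = spec$cif_alpha, perms = spec$cif_perms),
      store_rows = cif, row_ids = rows))
    inbag[[b]] <- rows
  }
  structure(list(method = spec$method, trees = trees, grid = grid,
                 is_cat = enc$is_cat, colnames = colnames(enc$Xm),
                 spec = spec, inbag = inbag,
                 train = list(y = data$y, delta = data$delta),
                 rotations = NULL),
            class = "fitted_forest")
}

#' Fit a random survival forest
#'
#' `B` bootstrap samples, one tree per sample, split criterion taken from
#' `spec$method` (log-rank, log-rank score, C-index, Brier or L1). Terminal
#' nodes store Nelson-Aalen cumulative hazards; ensemble predictions average
#' them on the training event-time grid.
#'
#' @param data a `surv_dataset`.
#' @param spec a [forest_spec()] with an `rsf_*` method.
#' @return object of class `fitted_forest`.
#' @export
fit_rsf <- function(data, spec) {
  stopifnot(startsWith(spec$method, "rsf_"))
  fit_forest_base(data, spec)
}

#' Impute censored observations from an ensemble survival distribution
#'
#' For every censored row the forest's conditional survival curve is
#' truncated to times beyond the censoring time and inverted at a uniform
#' draw; interior tail mass beyond the last grid point maps to the last
#' grid point. When no grid time exceeds the censoring time the imputed
#' time is drawn from an exponential tail extension (rate
#' `H(t_max)/t_max`), keeping every imputed time strictly beyond its
#' censoring time. Uncensored rows are untouched; the returned dataset is
#' fully uncensored.
#'
#' @param data the original `surv_dataset`.
#' @param forest a `fitted_forest` trained on `data`.
#' @param seed optional integer seed (local).
#' @export
impute_censored <- function(data, forest, seed = NULL) {
  cens <- which(data$delta == 0L)
  if (!length(cens)) return(data)
  curves <- predict_survival(forest, data$X[cens, , drop = FALSE])
  grid <- forest$grid
  y <- data$y
  with_seed(seed, {
    for (k in seq_along(cens)) {
      i <- cens[k]
      cv <- curves[[k]]
      ci <- data$y[i]
      sc <- eval_curve(cv, ci)
      u <- runif(1)
      cand <- which(grid > ci)
      if (!length(cand)) {
        hmax <- -log(max(min(cv$values), 1e-12))
        rate <- if (is.finite(hmax) && hmax > 0) hmax / max(grid) else 1 / mean(data$y)
        y[i] <- ci + rexp(1, rate)
      } else {
        hit <- cand[cv$values[cand] <= u * sc]
        y[i] <- if (length(hit)) grid[hit[1]] else grid[length(grid)]
      }
    }
  })
  surv_dataset(y, rep(1L, length(y)), data$X, t_true = data$t_true)
}

#' Fit recursively imputed survival trees (RIST)
#'
#' Grows `B` extremely randomized trees (one uniformly drawn cutpoint per
#' candidate covariate, best candidate by the log-rank statistic) on the
#' full sample, then alternates ensemble-based imputation of the censored
#' times with refitting, `rist_folds` times. Predictions come from the
#' final round's ensemble. With fully uncensored data imputation is a no-op
#' and the initial ensemble is returned unchanged.
#'
#' @param data a `surv_dataset`.
#' @param spec a [forest_spec()] with method `"rist"`.
#' @export
fit_rist <- function(data, spec) {
  stopifnot(spec$method == "rist")
  fit <- fit_forest_base(data, spec, ert = TRUE, rows_override = seq_along(data$y))
  if (!any(data$delta == 0L)) return(fit)
  grid <- fit$grid  # curves stay anchored to the observed event-time grid
  for (fold in seq_len(spec$rist_folds)) {
    imp <- impute_censored(data, fit, seed = derive_seed(spec$seed, 7, fold))
    sp <- spec
    sp$seed <- derive_seed(spec$seed, 13, fold)
    fit <- fit_forest_base(imp, sp, ert = TRUE,
                           rows_override = seq_along(imp$y), grid = grid)
  }
  fit
}

#' Fit a rotation survival forest (RotSF)
#'
#' Per tree: bootstrap sample; categorical covariates one-hot encoded; the
#' encoded columns are partitioned at random into subsets of
#' `rot_subset_size`; each subset receives its principal-axes rotation
#' computed on the bootstrap sample (identity fallback for constant
#' columns); the block-diagonal orthogonal matrix rotates the full encoded
#' matrix and a log-rank tree is grown on the rotated features. Rotations
#' are stored and re-applied at prediction.
#'
#' @param data a `surv_dataset`.
#' @param spec a [forest_spec()] with method `"rotsf"`.
#' @export
fit_rotsf <- function(data, spec) {
  stopifnot(spec$method == "rotsf")
  if (!any(data$delta == 1L))
    stop_named("sfb_no_events", "training data contains no events")
  Xe <- encode_onehot(data$X)
  n <- nrow(Xe); pe <- ncol(Xe)
  grid <- sort(unique(data$y[data$delta == 1L]))
  mtry <- spec$mtry %||% ceiling(sqrt(pe))
  trees <- vector("list", spec$n_trees)
  rots <- vector("list", spec$n_trees)
  inbag <- vector("list", spec$n_trees)
  for (b in seq_len(spec$n_trees)) {
    rows <- if (spec$bootstrap)
      draw_rows_with_events(n, data$delta, derive_seed(spec$seed, b, 1),
                            replace = TRUE)
      else seq_len(n)
    Q <- with_seed(derive_seed(spec$seed, b, 3), {
      perm <- sample.int(pe)
      blocks <- split(perm, ceiling(seq_along(perm) / spec$rot_subset_size))
      Q <- diag(pe)
      for (bl in blocks) {
        Xb <- Xe[rows, bl, drop = FALSE]
        if (any(apply(Xb, 2, stats::var) < 1e-12)) next  # identity fallback
        ev <- eigen(stats::cov(Xb), symmetric = TRUE)
        Q[bl, bl] <- ev$vectors
      }
      Q
    })
    Z <- Xe %*% Q
    trees[[b]] <- with_seed(derive_seed(spec$seed, b, 2), grow_tree_impl(
      data$y[rows], data$delta[rows], Z[rows, , drop = FALSE],
      rep(FALSE, pe), grid, "logrank", mtry, spec$min_node, spec$min_events))
    rots[[b]] <- Q
    inbag[[b]] <- rows
  }
  structure(list(method = "rotsf", trees = trees, grid = grid,
                 is_cat = rep(FALSE, pe), colnames = colnames(Xe),
                 spec = spec, inbag = inbag,
                 train = list(y = data$y, delta = data$delta),
                 rotations = rots),
            class = "fitted_forest")
}

#' Fit a conditional inference forest (CIF)
#'
#' Trees are grown on subsamples of `floor(0.632 n)` rows drawn without
#' replacement. At each node, a permutation-type independence test between
#' every candidate covariate and the survival outcome (linear statistics of
#' log-rank scores; asymptotic reference by default, exact permutation via
#' `cif_perms`) decides whether to split: when the smallest
#' Bonferroni-adjusted p-value exceeds `cif_alpha` the node becomes
#' terminal, otherwise the most significant covariate is split at its best
#' standardized-score cutpoint. Predictions aggregate via nearest-neighbour
#' weights (co-terminal training rows across trees) feeding a weighted
#' Kaplan-Meier.
#'
#' @param data a `surv_dataset`.
#' @param spec a [forest_spec()] with method `"cif"`.
#' @export
fit_cif <- function(data, spec) {
  stopifnot(spec$method == "cif")
  fit_forest_base(data, spec, cif = TRUE, subsample_frac = 0.632)
}

#' Fit any supported forest method
#'
#' Dispatcher used by the experiment runner.
#' @param data a `surv_dataset`.
#' @param spec a [forest_spec()].
#' @export
fit_forest <- function(data, spec) {
  switch(spec$method,
         rist = fit_rist(data, spec),
         rotsf = fit_rotsf(data, spec),
         cif = fit_cif(data, spec),
         fit_rsf(data, spec))
}

#' @export
print.fitted_forest <- function(x, ...) {
  cat(sprintf("<fitted_forest: %s, %d trees, grid of %d event times>\n",
              x$method, length(x$trees), length(x$grid)))
  invisible(x)
}

new_Xm_for_forest <- function(forest, Xnew) {
  if (forest$method %in% c("rotsf")) encode_onehot(Xnew)
  else encode_raw(Xnew)$Xm
}

#' Predict conditional survival curves
#'
#' Averaging methods (RSF family, RIST, RotSF) return
#' `S(t) = exp(-mean cumulative hazard)` across trees on the training
#' event-time grid; CIF returns the nearest-neighbour weighted
#' Kaplan-Meier. Unseen categorical levels are routed by the
#' majority-direction rule recorded at each split.
#'
#' @param forest a `fitted_forest`.
#' @param Xnew covariate matrix with the training columns.
#' @return list of survival-kind `survival_curve` objects.
#' @export
predict_survival <- function(forest, Xnew) {
  Xm <- new_Xm_for_forest(forest, Xnew)
  stopifnot(ncol(Xm) == length(forest$is_cat))
  nq <- nrow(Xm)
  G <- length(forest$grid)
  B <- length(forest$trees)
  if (forest$method == "cif") {
    ntr <- length(forest$train$y)
    W <- matrix(0, nq, ntr)
    for (b in seq_len(B)) {
      tr <- forest$trees[[b]]
      ids <- route_tree(tr, Xm)
      for (id in unique(ids)) {
        rows <- tr$nodes[[id]]$rows
        qs <- which(ids == id)
        W[qs, rows] <- W[qs, rows] + 1 / length(rows)
      }
    }
    W <- W / rowSums(W)
    lapply(seq_len(nq), function(i) {
      s <- weighted_km_on_grid(forest$train$y, forest$train$delta, W[i, ],
                               forest$grid)
      survival_curve(forest$grid, cummin(pmin(s, 1)), "survival")
    })
  } else {
    Hbar <- matrix(0, nq, G)
    for (b in seq_len(B)) {
      tr <- forest$trees[[b]]
      Z <- if (!is.null(forest$rotations)) Xm %*% forest$rotations[[b]] else Xm
      ids <- route_tree(tr, Z)
      Hmat <- do.call(rbind, lapply(tr$nodes[unique(ids)], `[[`, "H"))
      Hbar <- Hbar + Hmat[match(ids, unique(ids)), , drop = FALSE]
    }
    Hbar <- Hbar / B
    lapply(seq_len(nq), function(i)
      survival_curve(forest$grid, exp(-Hbar[i, ]), "survival"))
  }
}

#' Predicted median survival times for new data
#'
#' Convenience wrapper: [predict_survival()] followed by [predict_median()]
#' on each curve.
#' @inheritParams predict_survival
#' @export
predict_medians <- function(forest, Xnew) {
  vapply(predict_survival(forest, Xnew), predict_median, numeric(1))
}

# Structural summary used in tests: per-terminal-node unique event counts
# across all trees of a forest.
leaf_event_counts <- function(forest) {
  unlist(lapply(forest$trees, function(tr) {
    vapply(Filter(function(nd) nd$leaf, tr$nodes), `[[`, numeric(1),
           "n_unique_events")
  }))
}

# OOB masks: rows absent from a tree's bootstrap multiset.
oob_rows <- function(forest, b) {
  setdiff(seq_along(forest$train$y), unique(forest$inbag[[b]]))
}
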