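# Split statistics: all scores are "larger is better"; invalid splits get
# the -Inf sentinel and can never be selected.

# Pure-R standardized two-sample log-rank statistic (reference path; the
# per-node cutpoint scan uses the equivalent compiled routine).
lr_two_sample <- function(y, delta, left) {
  et <- sort(unique(y[delta == 1L]))
  num <- 0; v <- 0; evL <- 0L; evR <- 0L
  for (t in et) {
    at <- y >= t
    Y <- sum(at); Y1 <- sum(at & left)
    ev <- y == t & delta == 1L
    d <- sum(ev); d1 <- sum(ev & left)
    num <- num + d1 - d * Y1 / Y
    if (Y > 1) v <- v + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
    if (d1 > 0) evL <- evL + 1L
    if (d - d1 > 0) evR <- evR + 1L
  }
  list(num = num, var = v, ev_left = evL, ev_right = evR)
}

# Log-rank scores (martingale-residual form): a_i = delta_i - H_NA(y_i).
logrank_scores <- function(y, delta) {
  H <- nelson_aalen(y, delta)
  delta - eval_curve(H, y)
}

# Exact integral of |S_L - S_R| over the union event-time grid of the two
# children (step functions, so the integral is a finite sum).
l1_curve_distance <- function(yL, dL, yR, dR) {
  sL <- kaplan_meier(yL, dL)
  sR <- kaplan_meier(yR, dR)
  grid <- sort(unique(c(sL$times, sR$times)))
  if (length(grid) < 2) return(0)
  vL <- eval_curve(sL, grid)
  vR <- eval_curve(sR, grid)
  g <- length(grid)
  sum(diff(grid) * abs(vL - vR)[-g])
}

#' Score a candidate node split
#'
#' Evaluates one binary partition of a node under a chosen splitting
#' criterion; larger scores indicate stronger survival separation between
#' the children. Criteria:
#'
#' * `logrank`: absolute standardized two-sample log-rank statistic.
#' * `logrank_score`: rank-score standardization — the linear statistic of
#'   the log-rank scores `delta_i - H(y_i)` with permutation moments.
#' * `l1`: exact step-function integral of `|S_L - S_R|` over the union
#'   grid of the children's Kaplan-Meier event times.
#' * `cindex`: concordance of the left/right membership indicator used as a
#'   predictor, folded as `max(C, 1 - C)` so either direction of separation
#'   scores alike.
#' * `brier`: negative of the summed children Brier scores, each child
#'   scored against its own Kaplan-Meier estimate.
#'
#' A split is invalid (returns `-Inf`) when a child is empty or holds fewer
#' than `min_events` unique event times.
#'
#' @param y,delta observed times and event indicators of the node.
#' @param left_mask logical vector assigning rows to the left child.
#' @param criterion one of `"logrank"`, `"logrank_score"`, `"l1"`,
#'   `"cindex"`, `"brier"`.
#' @param min_events minimum unique event times required in each child.
#' @return scalar score (`-Inf` for invalid splits).
#' @export
split_statistic <- function(y, delta, left_mask,
                            criterion = c("logrank", "logrank_score", "l1",
                                          "cindex", "brier"),
                            min_events = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(length(y) == length(delta), length(y) == length(left_mask))
  nL <- sum(left_mask); nR <- sum(!left_mask)
  if (nL == 0L || nR == 0L) return(-Inf)
  uevL <- length(unique(y[left_mask & delta == 1L]))
  uevR <- length(unique(y[!left_mask & delta == 1L]))
  if (uevL < min_events || uevR < min_events) return(-Inf)
  switch(criterion,
    logrank = {
      lr <- lr_two_sample(y, delta, left_mask)
      if (lr$var <= 0) return(-Inf)
      abs(lr$num) / sqrt(lr$var)
    },
    logrank_score = {
      a <- logrank_scores(y, delta)
      m <- length(y)
      Tstat <- sum(a[left_mask])
      abar <- mean(a)
      v <- nL * nR / (m * (m - 1)) * sum((a - abar)^2)
      if (v <= 0) return(-Inf)
      abs(Tstat - nL * abar) / sqrt(v)
    },
    l1 = l1_curve_distance(y[left_mask], delta[left_mask],
                           y[!left_mask], delta[!left_mask]),
    cindex = {
      ce <- c_index_error(y, delta, as.numeric(left_mask))
      if (is.na(ce$E)) return(-Inf)
      C <- 1 - ce$E
      max(C, 1 - C)
    },
    brier = {
      w <- max(y)
      child_bs <- function(mask) {
        km <- kaplan_meier(y[mask], delta[mask])
        curves <- rep(list(km), sum(mask))
        sum(mask) * integrated_brier(curves, y[mask], w = w)
      }
      -(child_bs(left_mask) + child_bs(!left_mask))
    })
}

# Best cutpoint of a numeric covariate within a node under a criterion.
# `cuts = NULL` scans all midpoints of sorted unique values; a supplied
# vector (e.g. one random point for extremely randomized trees) restricts
# the scan. Returns NULL when no valid cut exists.
best_cut_numeric <- function(y, delta, x, criterion, min_node, min_events,
                             cuts = NULL) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  if (is.null(cuts)) cuts <- (ux[-1] + ux[-length(ux)]) / 2
  o <- order(y)
  if (criterion == "logrank") {
    sc <- lr_all_cuts_cpp(y[o], as.integer(delta[o]), x[o], cuts,
                          as.integer(min_node), as.integer(min_events))
  } else if (criterion == "logrank_score") {
    a <- logrank_scores(y, delta)
    m <- length(y)
    abar <- mean(a); ssa <- sum((a - abar)^2)
    ox <- order(x)
    xs <- x[ox]; as_ <- a[ox]
    csum <- cumsum(as_)
    nl <- findInterval(cuts, xs)
    Tc <- csum[pmax(nl, 1L)]
    v <- nl * (m - nl) / (m * (m - 1)) * ssa
    sc <- ifelse(nl >= 1L, abs(Tc - nl * abar) / sqrt(v), -Inf)
    # enforce node-size and child-event validity
    csum_d <- cumsum(delta[ox])
    totd <- sum(delta)
    bad <- nl < min_node | (m - nl) < min_node |
      csum_d[pmax(nl, 1L)] < min_events | (totd - csum_d[pmax(nl, 1L)]) < min_events |
      v <= 0 | nl < 1L
    sc[bad] <- -Inf
  } else {
    sc <- vapply(cuts, function(cc) {
      mask <- x <= cc
      if (sum(mask) < min_node || sum(!mask) < min_node) return(-Inf)
      split_statistic(y, delta, mask, criterion, min_events)
    }, numeric(1))
  }
  ok <- is.finite(sc)
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.max(sc[ok])]
  # deterministic tie-break: smallest cutpoint among exact score ties
  ties <- which(sc == sc[best])
  best <- ties[1]
  list(cut = cuts[best], score = sc[best])
}
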