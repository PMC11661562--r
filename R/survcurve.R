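#' Right-continuous survival / cumulative-hazard step curves
#'
#' A curve is a step function over a strictly increasing time grid with an
#' implicit value of 1 (survival) or 0 (cumulative hazard) at `t = 0`. An
#' empty grid encodes the trivial curve (no events observed).
#'
#' @param times strictly increasing, positive time grid.
#' @param values curve values at the grid points.
#' @param kind `"survival"` (non-increasing, in (0, 1] up to the last drop,
#'   where 0 is allowed) or `"cumulative_hazard"` (non-decreasing, >= 0).
#' @export
survival_curve <- function(times, values, kind = c("survival", "cumulative_hazard")) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(values))
  if (length(times)) {
    stopifnot(all(diff(times) > 0), all(times > 0))
    if (kind == "survival")
      stopifnot(all(values >= 0), all(values <= 1), all(diff(values) <= 1e-12))
    else
      stopifnot(all(values >= 0), all(diff(values) >= -1e-12))
  }
  structure(list(times = times, values = values, kind = kind),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve: %s on %d grid points>\n", x$kind,
              length(x$times)))
  invisible(x)
}

#' Evaluate a step curve at arbitrary times
#'
#' Right-continuous step evaluation; times before the first grid point get
#' the implicit baseline value (1 for survival, 0 for cumulative hazard).
#' @param curve a `survival_curve`.
#' @param t evaluation times.
#' @export
eval_curve <- function(curve, t) {
  base <- if (curve$kind == "survival") 1 else 0
  if (!length(curve$times)) return(rep(base, length(t)))
  idx <- findInterval(t, curve$times)
  ifelse(idx == 0L, base, curve$values[pmax(idx, 1L)])
}

# Counting-process summaries at sorted unique event times.
risk_table <- function(y, delta) {
  o <- order(y)
  y <- y[o]; delta <- delta[o]
  et <- unique(y[delta == 1L])
  if (!length(et))
    return(list(times = numeric(0), d = integer(0), n_risk = integer(0)))
  d <- vapply(et, function(t) sum(y == t & delta == 1L), numeric(1))
  n_risk <- length(y) - findInterval(et, y, left.open = TRUE)
  list(times = et, d = d, n_risk = n_risk)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param y observed times.
#' @param delta event indicators.
#' @return a survival-kind `survival_curve` on the sorted unique event times.
#' @export
kaplan_meier <- function(y, delta) {
  if (!length(y)) stop_named("sfb_empty", "empty input to kaplan_meier")
  rt <- risk_table(y, delta)
  survival_curve(rt$times, cumprod(1 - rt$d / rt$n_risk), "survival")
}

#' Nelson-Aalen cumulative-hazard estimator
#'
#' `H(t) = sum over event times <= t of d_j / n_j`; tied event times
#' contribute a single increment with `d_j` equal to the tie count.
#' @inheritParams kaplan_meier
#' @export
nelson_aalen <- function(y, delta) {
  if (!length(y)) stop_named("sfb_empty", "empty input to nelson_aalen")
  rt <- risk_table(y, delta)
  survival_curve(rt$times, cumsum(rt$d / rt$n_risk), "cumulative_hazard")
}

# Weighted Kaplan-Meier (weights >= 0, e.g. nearest-neighbour forest
# weights); returns survival values on `grid`.
weighted_km_on_grid <- function(y, delta, w, grid) {
  keep <- w > 0
  y <- y[keep]; delta <- delta[keep]; w <- w[keep]
  if (!length(y) || !any(delta == 1L)) return(rep(1, length(grid)))
  o <- order(y)
  y <- y[o]; delta <- delta[o]; w <- w[o]
  et <- unique(y[delta == 1L])
  dw <- vapply(et, function(t) sum(w[y == t & delta == 1L]), numeric(1))
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  nw <- tot - c(0, cw)[findInterval(et, y, left.open = TRUE) + 1L]
  s <- cumprod(pmax(0, 1 - dw / nw))
  idx <- findInterval(grid, et)
  ifelse(idx == 0L, 1, s[pmax(idx, 1L)])
}

#' Median (or maximum available quantile) of an estimated survival curve
#'
#' Returns the smallest grid time where the survival estimate drops to 0.5
#' or below; if the curve never reaches 0.5, returns the largest grid time
#' (the time of the maximum available quantile).
#' @param curve a survival-kind `survival_curve` with a non-empty grid.
#' @export
predict_median <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"), curve$kind == "survival")
  if (!length(curve$times))
    stop_named("sfb_empty", "empty survival curve has no median")
  hit <- which(curve$values <= 0.5)
  if (length(hit)) curve$times[hit[1]] else curve$times[length(curve$times)]
}

# Quick KM median used for ordering categorical levels inside trees;
# falls back to the largest observed time when no event time reaches 0.5
# and to max(y) when a level has no events at all.
km_median_quick <- function(y, delta) {
  if (!any(delta == 1L)) return(max(y))
  rt <- risk_table(y, delta)
  s <- cumprod(1 - rt$d / rt$n_risk)
  hit <- which(s <= 0.5)
  if (length(hit)) rt$times[hit[1]] else max(y)
}
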