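#' Mean absolute loss between true and predicted survival times
#'
#' `L = mean(|t_i - m_i|)` comparing latent (simulated) survival times with
#' predicted medians.
#' @param t_true latent survival times.
#' @param m_hat predicted median survival times.
#' @export
absolute_loss <- function(t_true, m_hat) {
  if (length(t_true) != length(m_hat) || !length(t_true))
    stop_named("sfb_length_mismatch",
               "t_true and m_hat must have equal positive length")
  mean(abs(t_true - m_hat))
}

#' Concordance-index prediction error under censoring
#'
#' Exact pairwise enumeration of Harrell's C-index with predicted medians
#' as the predicted outcome, returned in error form `E = 1 - C`:
#' all pairs `i < j` are formed; pairs whose shorter observed time is
#' censored, or with equal observed times both censored, are omitted
#' (non-permissible). For permissible pairs with unequal observed times the
#' pair counts 1 if the shorter observed time has the shorter prediction,
#' 0.5 if the predictions tie; for equal observed times the pair counts 1
#' if the predictions tie and 0.5 otherwise. `E = 0` is perfect ordering,
#' `E = 0.5` is random. With zero permissible pairs `E` is the `NA`
#' sentinel (never silently 0).
#'
#' @param y observed times.
#' @param delta event indicators.
#' @param m_hat predicted medians.
#' @return list with `E` and `n_permissible`.
#' @export
c_index_error <- function(y, delta, m_hat) {
  n <- length(y)
  if (length(delta) != n || length(m_hat) != n)
    stop_named("sfb_length_mismatch", "y, delta and m_hat must share length")
  if (n < 2L) return(list(E = NA_real_, n_permissible = 0L))
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  yi <- y[i]; yj <- y[j]; di <- delta[i]; dj <- delta[j]
  mi <- m_hat[i]; mj <- m_hat[j]
  eq <- yi == yj
  d_short <- ifelse(yi < yj, di, dj)
  permissible <- ifelse(eq, !(di == 0L & dj == 0L), d_short == 1L)
  m_short <- ifelse(yi < yj, mi, mj)
  m_long <- ifelse(yi < yj, mj, mi)
  cnt <- ifelse(eq,
                ifelse(mi == mj, 1, 0.5),
                ifelse(m_short < m_long, 1, ifelse(mi == mj, 0.5, 0)))
  np <- sum(permissible)
  if (np == 0L) return(list(E = NA_real_, n_permissible = 0L))
  C <- sum(cnt[permissible]) / np
  list(E = 1 - C, n_permissible = as.integer(np))
}

#' Integrated Brier score over estimated survival curves
#'
#' `IBS = (1/n) sum_i (1/w) integral_0^w (1(y_i > t) - S_hat(t|x_i))^2 dt`
#' with `w = max(y)` by default. Both the survival-status indicator and the
#' estimated curve are step functions, so the integral is computed exactly
#' over the merged breakpoints (curve grid, `y_i`, `w`); curves are
#' extended rightward as constants beyond their last grid point. No
#' censoring reweighting is applied by default, matching the definition
#' used here; an optional inverse-probability-of-censoring-weighted variant
#' is available via `ipcw` (off by default).
#'
#' @param curves list of survival-kind `survival_curve`, one per subject.
#' @param y observed times.
#' @param w upper integration limit (> 0); defaults to `max(y)`.
#' @param ipcw optional censoring survival curve (Kaplan-Meier of the
#'   censoring distribution); when supplied, Graf-style weights are applied.
#' @param delta event indicators, required only when `ipcw` is given.
#' @export
integrated_brier <- function(curves, y, w = NULL, ipcw = NULL, delta = NULL) {
  n <- length(y)
  stopifnot(length(curves) == n)
  w <- w %||% max(y)
  if (!is.numeric(w) || w <= 0)
    stop_named("sfb_bad_w", "integration limit w must be positive")
  total <- 0
  for (i in seq_len(n)) {
    cv <- curves[[i]]
    stopifnot(inherits(cv, "survival_curve"), cv$kind == "survival")
    bp <- sort(unique(c(0, cv$times[cv$times < w], min(y[i], w), w)))
    left <- bp[-length(bp)]
    len <- diff(bp)
    sv <- eval_curve(cv, left)
    ind <- as.numeric(y[i] >= bp[-1])
    seg <- (ind - sv)^2
    if (!is.null(ipcw)) {
      stopifnot(!is.null(delta))
      # Graf weights: 1/G(t) while subject at risk; 1/G(y_i-) after an event
      gy <- max(eval_curve(ipcw, y[i]), 1e-8)
      gt <- pmax(eval_curve(ipcw, left), 1e-8)
      wgt <- ifelse(y[i] >= bp[-1], 1 / gt,
                    if (delta[i] == 1L) 1 / gy else 0)
      seg <- seg * wgt
    }
    total <- total + sum(len * seg) / w
  }
  total / n
}

#' Response transforms used for downstream mixed-model analysis
#'
#' Adds `log(IBS)` and `log(log(L))` columns to a metric table; rows with
#' `L <= 1` (where `log(log(L))` is undefined) are flagged via
#' `loglog_valid`, never dropped silently.
#' @param df data.frame with columns `L` and `ibs`.
#' @export
metric_transforms <- function(df) {
  stopifnot(all(c("L", "ibs") %in% names(df)))
  df$log_ibs <- log(df$ibs)
  ok <- !is.na(df$L) & df$L > 1
  df$loglog_L <- NA_real_
  df$loglog_L[ok] <- log(log(df$L[ok]))
  df$loglog_valid <- ok
  df
}
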