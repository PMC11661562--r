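#' Enumerate the factor-level combinations of the simulation design
#'
#' Data factors and levels: response family (`weibull`, `aft`, `gg`),
#' linear-predictor form (`baseline`, `poly_int`, `sine`, `piecewise`),
#' censoring proportion (0.10, 0.25, 0.70), training sample size (200,
#' 1500) and extra variables (`baseline`, `correlated`, `noise`). The
#' `full` design crosses everything (3 x 4 x 3 x 2 x 3 = 216 combinations);
#' the `comprehensive` design drops the 25% censoring level
#' (3 x 4 x 2 x 2 x 3 = 144).
#'
#' @param design `"full"` or `"comprehensive"`.
#' @return data.frame with one row per factor-level combination (FLC).
#' @export
enumerate_flcs <- function(design = c("full", "comprehensive")) {
  if (length(design) != 1L || !design %in% c("full", "comprehensive"))
    stop_named("sfb_bad_design", "unknown design: %s",
               paste(design, collapse = ","))
  cens <- if (design == "full") c(0.10, 0.25, 0.70) else c(0.10, 0.70)
  flcs <- expand.grid(dgm_y = c("weibull", "aft", "gg"),
                      dgm_x = c("baseline", "poly_int", "sine", "piecewise"),
                      censoring = cens,
                      n_train = c(200L, 1500L),
                      extra = c("baseline", "correlated", "noise"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flcs$flc_id <- seq_len(nrow(flcs))
  flcs
}

#' Calibrate one factor-level combination
#'
#' Builds the default response model and linear-predictor specification for
#' the FLC, rescales the signal to the target SNR, then solves for the
#' exponential censoring rate that achieves the FLC's censoring proportion.
#'
#' @param flc one row of [enumerate_flcs()] (or a list with the same
#'   fields).
#' @param target_snr target signal-to-noise ratio.
#' @param n Monte Carlo size for both calibrations.
#' @param seed integer seed.
#' @param snr_tol,cens_tol calibration tolerances.
#' @return list with `model`, `spec`, `cens_rate`, `snr_report`,
#'   `censoring_calibration`.
#' @export
calibrate_flc <- function(flc, target_snr = 1, n = 2e4, seed = 1,
                          snr_tol = 0.02, cens_tol = 0.005) {
  model <- response_model_for(flc$dgm_y)
  spec <- lp_spec(flc$dgm_x)
  cal <- calibrate_signal(model, spec, target_snr = target_snr, tol = snr_tol,
                          n = n, seed = derive_seed(seed, 1))
  cc <- calibrate_censoring_rate(cal$model, cal$spec, target = flc$censoring,
                                 tol = cens_tol, n = n,
                                 seed = derive_seed(seed, 2))
  list(model = cal$model, spec = cal$spec, cens_rate = cc$rate,
       snr_report = cal$snr_report, censoring_calibration = cc)
}

#' Simulate one dataset from a calibrated factor-level combination
#'
#' @param flc one row of [enumerate_flcs()].
#' @param n sample size.
#' @param calib result of [calibrate_flc()].
#' @param seed integer seed; covariates, response and censoring use
#'   deterministic substreams so components are independently replayable.
#' @return a `surv_dataset` with latent times retained.
#' @export
simulate_flc_dataset <- function(flc, n, calib, seed) {
  X <- gen_covariates(n, flc$extra, seed = derive_seed(seed, 1))
  lp <- linear_predictor(X, calib$spec)
  t <- draw_survival_times(lp, calib$model, x1 = X[, "x1"],
                           seed = derive_seed(seed, 2))
  cc <- draw_censoring(n, calib$cens_rate, seed = derive_seed(seed, 3))
  assemble_dataset(t, cc, X)
}

#' Run a replicated method-by-FLC experiment
#'
#' For every (FLC, replicate) a training set of `n_train` rows and a test
#' set of `test_n` rows (latent times retained) are generated from the
#' calibrated mechanism; every method is fit on the identical training set
#' and evaluated with all three metrics on the identical test set. Seeds
#' are derived deterministically from `master_seed`, the FLC id and the
#' replicate, so results are replayable and independent of scheduling. A
#' method failure on a replicate is recorded (with the error message) and
#' the run continues.
#'
#' @param flcs data.frame of FLCs (rows of [enumerate_flcs()]).
#' @param methods character vector of forest methods (see [forest_spec()]).
#' @param R replicates per FLC.
#' @param master_seed integer master seed.
#' @param test_n test sample size.
#' @param calibrations optional list of [calibrate_flc()] results, one per
#'   row of `flcs`; computed on the fly (and cached per FLC) when omitted.
#' @param n_trees,mtry,min_node forest hyperparameters passed through.
#' @param calib_n Monte Carlo size for on-the-fly calibration.
#' @param target_snr SNR target for on-the-fly calibration.
#' @return data.frame of per-(FLC, method, replicate) metric records.
#' @export
run_experiment <- function(flcs, methods, R = 10, master_seed = 1,
                           test_n = 200, calibrations = NULL, n_trees = 100,
                           mtry = NULL, min_node = 6, calib_n = 2e4,
                           target_snr = 1) {
  out <- list()
  for (fi in seq_len(nrow(flcs))) {
    flc <- flcs[fi, ]
    calib <- if (!is.null(calibrations)) calibrations[[fi]]
      else calibrate_flc(flc, target_snr = target_snr, n = calib_n,
                         seed = derive_seed(master_seed, 999, flc$flc_id))
    for (r in seq_len(R)) {
      dseed <- derive_seed(master_seed, flc$flc_id, r)
      train <- simulate_flc_dataset(flc, flc$n_train, calib,
                                    seed = derive_seed(dseed, 1))
      test <- simulate_flc_dataset(flc, test_n, calib,
                                   seed = derive_seed(dseed, 2))
      train_checksum <- round(sum(train$y), 6)
      for (mi in seq_along(methods)) {
        meth <- methods[mi]
        fseed <- derive_seed(dseed, 3, mi)
        t0 <- proc.time()[["elapsed"]]
        rec <- tryCatch({
          spec <- forest_spec(meth, n_trees = n_trees, mtry = mtry,
                              min_node = min_node, seed = fseed)
          fit <- fit_forest(train, spec)
          curves <- predict_survival(fit, test$X)
          m_hat <- vapply(curves, predict_median, numeric(1))
          L <- absolute_loss(test$t_true, m_hat)
          ce <- c_index_error(test$y, test$delta, m_hat)
          ibs <- integrated_brier(curves, test$y)
          list(L = L, E = ce$E, n_permissible = ce$n_permissible,
               ibs = ibs, error = NA_character_)
        }, error = function(e) list(L = NA_real_, E = NA_real_,
                                    n_permissible = NA_integer_,
                                    ibs = NA_real_,
                                    error = conditionMessage(e)))
        out[[length(out) + 1L]] <- data.frame(
          flc_id = flc$flc_id, dgm_y = flc$dgm_y, dgm_x = flc$dgm_x,
          censoring = flc$censoring, n_train = flc$n_train,
          extra = flc$extra, method = meth, replicate = r,
          L = rec$L, E = rec$E, n_permissible = rec$n_permissible,
          ibs = rec$ibs, seed = fseed, train_checksum = train_checksum,
          runtime = proc.time()[["elapsed"]] - t0, error = rec$error,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("result_table", "data.frame")
  res
}

# Methods excluded from a metric's summaries (coarse-grid methods are not
# comparable on the integrated Brier score).
metric_exclusions <- function(metric) {
  if (metric == "ibs") "rsf_l1" else character(0)
}

#' Relative-mean summary of an experiment
#'
#' For each metric: the sample mean across replicates is computed per
#' (FLC, method) and centred around the across-method mean for that FLC,
#' so negative values indicate better-than-average performance. Methods
#' excluded from a metric (L1 for the integrated Brier score) are dropped
#' before centring.
#'
#' @param results a `result_table` from [run_experiment()].
#' @param metric `"L"`, `"E"` or `"ibs"`.
#' @return data.frame with one centred value per (FLC, method).
#' @export
relative_mean_summary <- function(results, metric = c("L", "E", "ibs")) {
  metric <- match.arg(metric)
  res <- results[!results$method %in% metric_exclusions(metric), ]
  if (length(unique(res$method)) < 2L)
    stop_named("sfb_too_few_methods",
               "relative means need at least two methods per FLC")
  agg <- stats::aggregate(res[[metric]],
                          by = list(flc_id = res$flc_id, method = res$method),
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "mean_value"
  centre <- stats::ave(agg$mean_value, agg$flc_id)
  agg$centered <- agg$mean_value - centre
  agg$metric <- metric
  agg[order(agg$flc_id, agg$method), ]
}

#' Export tidy per-replicate results for external modelling
#'
#' Writes (or returns) a table with the raw metrics, the modelling
#' transforms `log(ibs)` and `log(log(L))` (rows with `L <= 1` flagged via
#' `loglog_valid`), factor columns, and a `dataset_id` column identifying
#' the shared (FLC, replicate) dataset for dataset-level random effects.
#'
#' @param results a `result_table`.
#' @param file optional CSV path.
#' @return the tidy data.frame, invisibly when `file` is given.
#' @export
export_tidy <- function(results, file = NULL) {
  df <- as.data.frame(results)
  df$dataset_id <- if (nrow(df)) paste0("flc", df$flc_id, "_rep", df$replicate)
    else character(0)
  if (nrow(df)) df <- metric_transforms(df)
  else {
    df$log_ibs <- numeric(0); df$loglog_L <- numeric(0)
    df$loglog_valid <- logical(0)
  }
  if (!is.null(file)) {
    write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
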