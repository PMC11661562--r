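# Shared fixture builders (all data generated in code at test time).

# Small Weibull proportional-hazards dataset on the base 10-covariate design.
make_weibull_data <- function(n = 120, seed = 1, cens_rate = 0.3,
                              dgm_x = "baseline") {
  X <- gen_covariates(n, "baseline", seed = seed)
  spec <- lp_spec(dgm_x)
  t <- draw_survival_times(linear_predictor(X, spec), response_weibull(),
                           x1 = X[, "x1"], seed = seed + 1)
  assemble_dataset(t, draw_censoring(n, cens_rate, seed = seed + 2), X)
}

# Covariate matrix of independent uniforms (no categoricals), for engine
# tests that need purely numeric features.
make_uniform_X <- function(n, p, seed = 1) {
  X <- with_seed_local(seed, matrix(runif(n * p), n, p))
  colnames(X) <- paste0("v", seq_len(p))
  attr(X, "column_kind") <- rep("uniform", p)
  class(X) <- c("covariate_matrix", "matrix", "array")
  X
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Survival data with a single strongly prognostic binary covariate whose
# groups occupy disjoint time ranges, plus one noise column.
make_separable_data <- function(n = 60, seed = 2) {
  X <- with_seed_local(seed, {
    cbind(g = rep(c(0, 1), each = n / 2), z = runif(n))
  })
  attr(X, "column_kind") <- c("binary", "uniform")
  class(X) <- c("covariate_matrix", "matrix", "array")
  y <- with_seed_local(seed + 1,
                       c(runif(n / 2, 1, 2), runif(n / 2, 5, 6)))
  surv_dataset(y, rep(1L, n), X)
}
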