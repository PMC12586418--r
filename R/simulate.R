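# True predictor coefficients of the simulation study: the five informative
# covariates act as  eta_muT = b0 + 2 x1 + x3,  eta_sigmaT = 0.7 + 0.7 x3,
# eta_muC = b0 - x2 + 1.5 x4,  eta_sigmaC = 0.5 x2,  and the dependence
# predictor depends on the scenario.
.SIM_MARGIN_COEF <- list(
  mu_T    = c(x1 = 2, x3 = 1),
  sigma_T = c(x3 = 0.7),
  mu_C    = c(x2 = -1, x4 = 1.5),
  sigma_C = c(x2 = 0.5))
.SIM_SIGMA_INTERCEPTS <- c(sigma_T = 0.7, sigma_C = 0)

# intercept pairs (b0_muT, b0_muC) calibrated to average censoring rates
.SIM_INTERCEPTS <- list(
  weibull   = list(`20` = c(-1, 0.8), `50` = c(0.7, 0.8), `80` = c(1, -0.4)),
  lognormal = list(`20` = c(-0.9, 0.8), `50` = c(1, 0.8), `80` = c(1.5, -0.4)))

#' Simulation scenario description
#'
#' Describes one scenario of the dependent-censoring simulation study.
#' Setting 1 uses the dependence predictor \eqn{\eta_\rho = 2 + 1.5 x_5}
#' (strong positive association); Setting 2 (Gaussian copula only) uses
#' \eqn{\eta_\rho = 0.25 + 0.4 x_1 - 0.6 x_5} (weaker, partly negative);
#' Setting 3 fixes \eqn{\eta_\rho = 0} (conditionally independent censoring).
#' Both margins share one family; covariates are i.i.d. Uniform(-1, 1) and
#' shared across all five predictors, so `p_per_parameter` columns are
#' generated and the total availability is `p_star = 5 * p_per_parameter`.
#'
#' @param setting 1, 2 or 3.
#' @param margin `"weibull"` or `"lognormal"` (used for both margins).
#' @param copula `"clayton"`, `"gaussian"` or `"gumbel"`.
#' @param censoring target average censoring percentage: 20, 50 or 80.
#'   Selects the calibrated marginal location intercept pair; ignored when
#'   `intercepts` is given directly.
#' @param intercepts optional numeric pair `(b0_muT, b0_muC)` overriding the
#'   calibrated values.
#' @param p_per_parameter number of covariate columns available to each
#'   predictor (>= 5; the first five are informative).
#' @param n sample size.
#' @param seed integer seed.
#' @export
simulation_setting <- function(setting = 1,
                               margin = c("weibull", "lognormal"),
                               copula = c("gaussian", "clayton", "gumbel"),
                               censoring = 20, intercepts = NULL,
                               p_per_parameter = 10, n = 1000, seed = 1) {
  margin <- match.arg(margin)
  copula <- match.arg(copula)
  if (!setting %in% 1:3) .stopf("'setting' must be 1, 2 or 3")
  if (setting == 2 && copula != "gaussian")
    .stopf("Setting 2 is defined for the Gaussian copula only")
  if (p_per_parameter < 5)
    .stopf("'p_per_parameter' must be at least 5 (x1..x5 are informative)")
  if (is.null(intercepts)) {
    key <- as.character(censoring)
    if (!key %in% names(.SIM_INTERCEPTS[[margin]]))
      .stopf("no calibrated intercept pair for %s margins at %s%% censoring",
             margin, key)
    intercepts <- .SIM_INTERCEPTS[[margin]][[key]]
  }
  rho_coef <- switch(as.character(setting),
    `1` = list(intercept = 2, coefs = c(x5 = 1.5)),
    `2` = list(intercept = 0.25, coefs = c(x1 = 0.4, x5 = -0.6)),
    `3` = list(intercept = 0, coefs = numeric(0)))
  structure(list(setting = setting, margin = margin, copula = copula,
                 intercepts = intercepts, rho_coef = rho_coef,
                 p_per_parameter = as.integer(p_per_parameter),
                 p_star = 5L * as.integer(p_per_parameter),
                 n = as.integer(n), seed = as.integer(seed)),
            class = "simulation_setting")
}

#' @export
print.simulation_setting <- function(x, ...) {
  cat(sprintf(
    "<simulation_setting> Setting %d: %s margins, %s copula, n = %d, p* = %d\n",
    x$setting, x$margin, x$copula, x$n, x$p_star))
  invisible(x)
}

# evaluate the true eta matrix for a covariate matrix
.sim_true_eta <- function(setting, X) {
  n <- nrow(X)
  eta <- matrix(0, n, 5, dimnames = list(NULL, .PARAM_NAMES))
  eta[, "mu_T"] <- setting$intercepts[1]
  eta[, "mu_C"] <- setting$intercepts[2]
  eta[, "sigma_T"] <- .SIM_SIGMA_INTERCEPTS[["sigma_T"]]
  eta[, "sigma_C"] <- .SIM_SIGMA_INTERCEPTS[["sigma_C"]]
  for (k in names(.SIM_MARGIN_COEF))
    for (v in names(.SIM_MARGIN_COEF[[k]]))
      eta[, k] <- eta[, k] + .SIM_MARGIN_COEF[[k]][[v]] * X[, v]
  eta[, "rho"] <- setting$rho_coef$intercept
  for (v in names(setting$rho_coef$coefs))
    eta[, "rho"] <- eta[, "rho"] + setting$rho_coef$coefs[[v]] * X[, v]
  eta
}

#' Generate a dataset from a simulation scenario
#'
#' Pipeline: draw covariates, evaluate the true additive predictors, invert
#' the links, sample dependent uniform pairs from the copula at the row-wise
#' dependence parameter, invert the margins to latent `(T, C)` and release
#' `Y = min(T, C)`, `delta = 1{T <= C}`.
#'
#' @param setting a [simulation_setting()].
#' @return list with elements `data` (a [survival_dataset()]) and `truth`
#'   (a `sim_truth` with latent times, per-row true parameters and the model
#'   spec, usable as an evaluation oracle).
#' @export
simulate_setting <- function(setting) {
  stopifnot(inherits(setting, "simulation_setting"))
  set.seed(setting$seed)
  n <- setting$n; p <- setting$p_per_parameter
  X <- matrix(stats::runif(n * p, -1, 1), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- .sim_true_eta(setting, X)
  mspec <- model_spec(margin_spec(setting$margin), margin_spec(setting$margin),
                      copula_spec(setting$copula))
  params <- .params_from_eta(mspec, eta)
  uv <- sample_pair(mspec$copula, params[, "theta"])
  T_lat <- margin_quantile(mspec$margin_T, uv[, "u"],
                           params[, "mu_T"], params[, "sigma_T"])
  C_lat <- margin_quantile(mspec$margin_C, uv[, "v"],
                           params[, "mu_C"], params[, "sigma_C"])
  y <- pmin(T_lat, C_lat)
  delta <- as.numeric(T_lat <= C_lat)
  truth <- structure(list(T = T_lat, C = C_lat, params = params, eta = eta,
                          spec = mspec, setting = setting, X = X),
                     class = "sim_truth")
  list(data = survival_dataset(y, delta, X), truth = truth)
}

#' Generate train / validation / test replicates of one scenario
#'
#' Fresh independent draws with seeds `seed`, `seed + 1`, `seed + 2`.
#'
#' @inheritParams simulate_setting
#' @param n_val,n_test sample sizes of the auxiliary sets.
#' @export
simulate_replicate <- function(setting, n_val = 1000, n_test = 1000) {
  s_val <- setting; s_val$n <- as.integer(n_val); s_val$seed <- setting$seed + 1L
  s_test <- setting; s_test$n <- as.integer(n_test); s_test$seed <- setting$seed + 2L
  list(train = simulate_setting(setting),
       val = simulate_setting(s_val),
       test = simulate_setting(s_test))
}

#' True survival and censoring survival oracles
#'
#' Exact margin survival functions at the true per-row parameters of a
#' simulated dataset: `true_survival` returns \eqn{S(t|x_i) = P(T > t|x_i)},
#' `true_censor_survival` returns \eqn{G(t|x_i) = P(C > t|x_i)}.
#'
#' @param truth a `sim_truth` from [simulate_setting()].
#' @param t vector of positive times.
#' @param rows optional row indices (default: all rows).
#' @return matrix with one row per subject, one column per time.
#' @export
true_survival <- function(truth, t, rows = NULL) {
  .truth_surv(truth, t, rows, margin = "T")
}

#' @rdname true_survival
#' @export
true_censor_survival <- function(truth, t, rows = NULL) {
  .truth_surv(truth, t, rows, margin = "C")
}

.truth_surv <- function(truth, t, rows, margin) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(rows)) rows <- seq_len(nrow(truth$params))
  spec <- if (margin == "T") truth$spec$margin_T else truth$spec$margin_C
  mu <- truth$params[rows, paste0("mu_", margin)]
  sigma <- truth$params[rows, paste0("sigma_", margin)]
  out <- vapply(t, function(ti) 1 - margin_cdf(spec, ti, mu, sigma),
                numeric(length(rows)))
  matrix(out, nrow = length(rows))
}
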