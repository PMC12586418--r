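#' Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimator applied to the censoring distribution (event
#' indicator `1 - delta`), as used for the IPCW weights of the AFT
#' benchmark.  Returns a right-continuous nonincreasing step function with
#' `G(0) = 1`.
#'
#' @param data a [survival_dataset()].
#' @return a function `G(t)`.
#' @export
km_censoring_survival <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  sf <- survival::survfit(survival::Surv(data$y, 1 - data$delta) ~ 1)
  stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
}

.G_FLOOR <- 1e-4   # IPCW weight floor: caps unbounded tail weights

# evaluate a censoring-survival callable; returns n x T matrix.
# G_hat(t) -> vector (marginal, e.g. KM) or G_hat(t, X) -> matrix (conditional)
.eval_G <- function(G_hat, times, X) {
  n <- nrow(X)
  if (length(formals(G_hat)) >= 2) {
    out <- G_hat(times, X)
    matrix(out, nrow = n)
  } else {
    matrix(rep(G_hat(times), each = n), nrow = n)
  }
}

#' Censoring-weighted Brier score
#'
#' For each grid time `t`,
#' \deqn{BS(t) = n^{-1}\sum_i [\hat S(t|x_i)^2 I(Y_i \le t, \delta_i = 1)/
#'   \hat G(Y_i) + (1-\hat S(t|x_i))^2 I(Y_i > t)/\hat G(t)],}
#' where the censoring-survival weights are either marginal (Kaplan-Meier,
#' `G_hat(t)`) or conditional on covariates (`G_hat(t, X)`, in which case
#' the weights become \eqn{\hat G(Y_i|x_i)} and \eqn{\hat G(t|x_i)}).
#' Weights are floored at 1e-4 with a warning.  The summary scalar is the
#' unweighted mean of `BS(t)` over the grid.
#'
#' @param test a [survival_dataset()] of evaluation subjects.
#' @param S_hat callable `S_hat(times, X)` returning an n x T matrix of
#'   predicted survival probabilities.
#' @param G_hat censoring-survival callable (see above).
#' @param times evaluation grid; defaults to the sorted observed test times.
#' @return object of class `metric_series` with fields `times`, `values`,
#'   `summary` and `weighting`.
#' @export
brier_score <- function(test, S_hat, G_hat, times = NULL) {
  stopifnot(inherits(test, "survival_dataset"))
  if (is.null(times)) times <- sort(test$y)
  n <- length(test$y)
  conditional <- length(formals(G_hat)) >= 2
  S <- matrix(S_hat(times, test$X), nrow = n)
  Gt <- .eval_G(G_hat, times, test$X)
  # per-subject weight at the subject's own observed time
  if (conditional) {
    GY <- diag(.eval_G(G_hat, test$y, test$X))
  } else {
    GY <- G_hat(test$y)
  }
  n_floored <- sum(Gt < .G_FLOOR) + sum(GY < .G_FLOOR)
  if (n_floored > 0)
    warning(sprintf("censoring-survival weights floored at %g in %d cells",
                    .G_FLOOR, n_floored))
  Gt <- pmax(Gt, .G_FLOOR); GY <- pmax(GY, .G_FLOOR)
  past_event <- outer(test$y, times, "<=") * (test$delta == 1)  # I(Y<=t, d=1)
  at_risk <- outer(test$y, times, ">")                          # I(Y > t)
  bs <- colMeans(S^2 * past_event / GY + (1 - S)^2 * at_risk / Gt)
  structure(list(times = times, values = bs, summary = mean(bs),
                 weighting = if (conditional) "model-conditional" else "marginal"),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %d grid times, %s weights, summary = %.4f\n",
              length(x$times), x$weighting, x$summary))
  invisible(x)
}

#' Integrated absolute error between survival curves
#'
#' \eqn{IAE = n^{-1}\sum_i \int_0^{t_{max}} |S(t|x_i) - \hat S(t|x_i)| dt},
#' computed by the trapezoidal rule on a fixed 512-point grid over
#' `[0, t_max]` (by convention `t_max` is the largest observed test time).
#'
#' @param S_true callable `S_true(times, X)` returning an n x T matrix.
#' @param S_hat callable of the same shape.
#' @param X_test covariate matrix of the evaluation subjects.
#' @param t_max upper integration limit (> 0).
#' @param quad_points number of grid points (default 512).
#' @export
iae <- function(S_true, S_hat, X_test, t_max, quad_points = 512) {
  if (t_max <= 0) .stopf("'t_max' must be positive")
  X_test <- as.matrix(X_test)
  grid <- seq(0, t_max, length.out = quad_points)
  tg <- pmax(grid, 1e-12)   # survival functions are defined for t > 0
  n <- nrow(X_test)
  A <- abs(matrix(S_true(tg, X_test), nrow = n) -
             matrix(S_hat(tg, X_test), nrow = n))
  dt <- grid[2] - grid[1]
  per_row <- (rowSums(A) - 0.5 * (A[, 1] + A[, quad_points])) * dt
  mean(per_row)
}

#' Evaluate a boosted fit on a test set
#'
#' Copula mode weights the Brier score by the fitted model's conditional
#' censoring survival \eqn{\hat G(t|x)}; AFT mode uses the Kaplan-Meier
#' estimate of the censoring distribution from the test set.  When a truth
#' oracle is supplied, integrated absolute errors against the true survival
#' function (and, in copula mode, the true censoring survival) are added.
#'
#' @param fit a `boost_fit`.
#' @param test a [survival_dataset()].
#' @param truth optional `sim_truth` for the test rows.
#' @param mode `"copula"` or `"aft"`; defaults to the fit's own type.
#' @return list with `brier` (a `metric_series`), `brier_summary`, and when
#'   truth is available `iae_survival` (plus `iae_censoring` in copula mode).
#' @export
evaluate_fit <- function(fit, test, truth = NULL, mode = NULL) {
  stopifnot(inherits(fit, "boost_fit"))
  if (is.null(mode)) mode <- fit$type
  mode <- match.arg(mode, c("copula", "aft"))
  S_hat <- function(t, X) predict(fit, X, type = "survival", times = t)
  if (mode == "copula") {
    G_hat <- function(t, X) predict(fit, X, type = "censor_survival", times = t)
  } else {
    km <- km_censoring_survival(test)
    G_hat <- function(t) km(t)
  }
  bs <- brier_score(test, S_hat, G_hat)
  out <- list(brier = bs, brier_summary = bs$summary, mode = mode,
              mstop = fit$mstop)
  if (!is.null(truth)) {
    t_max <- max(test$y)
    out$iae_survival <- iae(function(t, X) true_survival(truth, t),
                            S_hat, test$X, t_max)
    if (mode == "copula")
      out$iae_censoring <- iae(function(t, X) true_censor_survival(truth, t),
                               G_hat, test$X, t_max)
  }
  out
}
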