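# shared fixtures and independent finite-difference oracles

ALL_MARGINS <- c("weibull", "lognormal")
ALL_COPULAS <- c("clayton", "gaussian", "gumbel")

# random theta draw inside each family's sensible range
rand_theta <- function(family, n) {
  switch(family,
    clayton  = stats::runif(n, 0.2, 5),
    gaussian = stats::runif(n, -0.9, 0.9),
    gumbel   = stats::runif(n, 1.1, 6))
}

# small random dataset with moderate predictor coefficients
make_random_problem <- function(margin, copula, n = 20, p = 3, seed = 1) {
  set.seed(seed)
  spec <- model_spec(margin_spec(margin), margin_spec(margin),
                     copula_spec(copula))
  X <- matrix(stats::runif(n * p, -1, 1), n, p)
  data <- survival_dataset(exp(stats::rnorm(n)), stats::rbinom(n, 1, 0.5), X)
  coeffs <- predictor_coefficients(c(0.2, 0.1, -0.1, 0.05, 0.3),
                                   matrix(stats::rnorm(p * 5, sd = 0.3), p, 5),
                                   colMeans(X))
  list(spec = spec, data = data, coeffs = coeffs)
}

# central finite differences of neg_loglik under per-observation perturbation
# of a single predictor column: the independent oracle for neg_gradients
fd_neg_gradients <- function(spec, coeffs, data, eps = 1e-6) {
  eta <- copboost:::eval_predictors(coeffs, data$X)
  n <- nrow(eta); K <- ncol(eta)
  fd <- matrix(0, n, K)
  for (k in seq_len(K)) for (i in seq_len(n)) {
    ep <- eta; ep[i, k] <- ep[i, k] + eps
    em <- eta; em[i, k] <- em[i, k] - eps
    fd[i, k] <-
      (-sum(copboost:::.copula_loglik_eta(spec, ep, data$y, data$delta)) +
        sum(copboost:::.copula_loglik_eta(spec, em, data$y, data$delta))) /
      (2 * eps)
  }
  fd
}

fd_aft_neg_gradients <- function(margin, coeffs, data, eps = 1e-6) {
  eta <- copboost:::eval_predictors(coeffs, data$X)
  n <- nrow(eta)
  fd <- matrix(0, n, 2)
  for (k in 1:2) for (i in seq_len(n)) {
    ep <- eta; ep[i, k] <- ep[i, k] + eps
    em <- eta; em[i, k] <- em[i, k] - eps
    fd[i, k] <-
      (-sum(copboost:::.aft_loglik_eta(margin, ep, data$y, data$delta)) +
        sum(copboost:::.aft_loglik_eta(margin, em, data$y, data$delta))) /
      (2 * eps)
  }
  fd
}

expect_rel_equal <- function(actual, expected, tol, floor = 1) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), floor)), tol)
}
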