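#' Right-censored survival dataset
#'
#' Container for one row per subject: observed time `y = min(T, C)`, event
#' indicator `delta = 1` if the event was observed (`T <= C`) and 0 if
#' censored, plus a numeric covariate matrix.
#'
#' @param y positive observed times.
#' @param delta event indicators in `{0, 1}`.
#' @param X numeric covariate matrix with `length(y)` rows (may have 0
#'   columns).
#' @param names optional covariate labels; defaults to the column names of
#'   `X` or `x1, x2, ...`.
#' @return object of class `survival_dataset`.
#' @export
survival_dataset <- function(y, delta, X, names = NULL) {
  y <- as.numeric(y); delta <- as.numeric(delta)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (n < 1L) .stopf("dataset must contain at least one observation")
  if (any(!is.finite(y)) || any(y <= 0)) {
    bad <- which(!is.finite(y) | y <= 0)[1]
    .stopf("observed times must be positive and finite (row %d: y = %s)",
           bad, format(y[bad]))
  }
  if (!all(delta %in% c(0, 1))) {
    bad <- which(!delta %in% c(0, 1))[1]
    .stopf("event indicator must be 0 or 1 (row %d: delta = %s)",
           bad, format(delta[bad]))
  }
  if (nrow(X) != n) .stopf("covariate matrix must have %d rows", n)
  if (any(!is.finite(X))) .stopf("covariates must be finite (no missing values)")
  if (is.null(names)) names <- colnames(X)
  if (is.null(names) && ncol(X) > 0) names <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- names
  structure(list(y = y, delta = delta, X = X, names = names),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> n = %d, p = %d, events = %d (%.1f%%)\n",
              length(x$y), ncol(x$X), sum(x$delta),
              100 * mean(x$delta)))
  invisible(x)
}

#' Joint model specification
#'
#' Combines a survival margin, a censoring margin and a copula into the joint
#' observed-data model for `(Y, delta)`.  Identifiability restricts the
#' margins to Weibull or log-normal and the copula to Clayton, Gaussian or
#' Gumbel.
#'
#' @param margin_T,margin_C [margin_spec()] objects for T and C.
#' @param copula a [copula_spec()].
#' @export
model_spec <- function(margin_T, margin_C, copula) {
  stopifnot(inherits(margin_T, "margin_spec"),
            inherits(margin_C, "margin_spec"),
            inherits(copula, "copula_spec"))
  structure(list(margin_T = margin_T, margin_C = margin_C, copula = copula),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> T: %s, C: %s, copula: %s\n",
              x$margin_T$family, x$margin_C$family, x$copula$family))
  invisible(x)
}

.PARAM_NAMES <- c("mu_T", "sigma_T", "mu_C", "sigma_C", "rho")

#' Predictor coefficients for all five additive predictors
#'
#' Linear predictors \eqn{\eta_k(x) = \beta_{0k} + (x - \bar x)^\top \beta_k}
#' for each distribution parameter `k` in (mu_T, sigma_T, mu_C, sigma_C,
#' rho); covariates are centered by the stored column means.
#'
#' @param intercepts numeric vector of length K (one per predictor).
#' @param beta p x K coefficient matrix (p may be 0).
#' @param centers length-p vector of covariate centering means.
#' @param param_names labels for the K predictors.
#' @export
predictor_coefficients <- function(intercepts, beta, centers,
                                   param_names = .PARAM_NAMES) {
  beta <- as.matrix(beta)
  K <- length(intercepts)
  if (ncol(beta) != K) .stopf("'beta' must have %d columns", K)
  if (length(centers) != nrow(beta))
    .stopf("'centers' must have length %d", nrow(beta))
  colnames(beta) <- param_names
  names(intercepts) <- param_names
  structure(list(intercepts = intercepts, beta = beta, centers = centers,
                 param_names = param_names),
            class = "predictor_coefficients")
}

# evaluate all additive predictors at X -> n x K matrix
eval_predictors <- function(coeffs, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(coeffs$beta))
    .stopf("covariate matrix has %d columns but coefficients expect %d",
           ncol(X), nrow(coeffs$beta))
  n <- nrow(X)
  eta <- matrix(coeffs$intercepts, n, length(coeffs$intercepts), byrow = TRUE)
  if (ncol(X) > 0)
    eta <- eta + sweep(X, 2, coeffs$centers) %*% coeffs$beta
  colnames(eta) <- coeffs$param_names
  eta
}

#' Natural-scale distribution parameters at covariate values
#'
#' Evaluates the five additive predictors and maps them through the inverse
#' link functions to (mu_T, sigma_T, mu_C, sigma_C, theta).
#'
#' @param spec a [model_spec()].
#' @param coeffs a [predictor_coefficients()] object with K = 5 predictors.
#' @param X covariate matrix.
#' @return n x 5 matrix of natural-scale parameters.
#' @export
params_at <- function(spec, coeffs, X) {
  eta <- eval_predictors(coeffs, X)
  .params_from_eta(spec, eta)
}

.params_from_eta <- function(spec, eta) {
  mT <- .margin_link_inv(spec$margin_T, eta[, 1], eta[, 2])
  mC <- .margin_link_inv(spec$margin_C, eta[, 3], eta[, 4])
  theta <- copula_link_inv(spec$copula, eta[, 5])
  out <- cbind(mu_T = mT$mu, sigma_T = mT$sigma,
               mu_C = mC$mu, sigma_C = mC$sigma, theta = theta)
  out
}

.params_as_matrix <- function(params) {
  if (is.list(params) && !is.matrix(params))
    params <- do.call(cbind, params[c("mu_T", "sigma_T", "mu_C", "sigma_C",
                                      "theta")])
  params
}

#' Distribution function of the observed time Y
#'
#' \eqn{F_Y(y) = F_T(y) + F_C(y) - C\{F_T(y), F_C(y) \mid \theta\}}.
#'
#' @param spec a [model_spec()].
#' @param params n x 5 matrix (or named list) of natural-scale parameters
#'   with columns `mu_T, sigma_T, mu_C, sigma_C, theta`.
#' @param y positive times.
#' @export
observed_cdf_Y <- function(spec, params, y) {
  p <- .params_as_matrix(params)
  FT <- margin_cdf(spec$margin_T, y, p[, 1], p[, 2])
  FC <- margin_cdf(spec$margin_C, y, p[, 3], p[, 4])
  pmin(pmax(FT + FC - copula_cdf(spec$copula, FT, FC, p[, 5]), 0), 1)
}

#' Density of the observed time Y and its likelihood parts
#'
#' The observed-data density decomposes into the event contribution
#' \eqn{f_T(y)[1 - h_{C|T}\{F_C(y) \mid F_T(y)\}]} and the censoring
#' contribution \eqn{f_C(y)[1 - h_{T|C}\{F_T(y) \mid F_C(y)\}]}; `part`
#' selects either contribution or their sum.
#'
#' @inheritParams observed_cdf_Y
#' @param part `"both"`, `"event"` or `"censored"`.
#' @export
observed_density_Y <- function(spec, params, y,
                               part = c("both", "event", "censored")) {
  part <- match.arg(part)
  if (any(y <= 0)) .stopf("times must be positive")
  p <- .params_as_matrix(params)
  u <- .clip01(margin_cdf(spec$margin_T, y, p[, 1], p[, 2]))
  v <- .clip01(margin_cdf(spec$margin_C, y, p[, 3], p[, 4]))
  ev <- cs <- 0
  if (part %in% c("both", "event")) {
    fT <- margin_pdf(spec$margin_T, y, p[, 1], p[, 2])
    ev <- fT * (1 - .h_vgu(spec$copula, u, v, p[, 5]))
  }
  if (part %in% c("both", "censored")) {
    fC <- margin_pdf(spec$margin_C, y, p[, 3], p[, 4])
    cs <- fC * (1 - .h_vgu(spec$copula, v, u, p[, 5]))
  }
  pmax(ev + cs, 0)
}

#' Conditional censoring survival function
#'
#' \eqn{\hat G(t \mid x) = 1 - F_C(t \mid \theta_C(x))}, the model-based
#' estimate of `P(C > t | x)` used as the IPCW weight of the
#' censoring-weighted Brier score.
#'
#' @inheritParams params_at
#' @param t positive times.
#' @param X covariate matrix (one row per subject).
#' @return matrix with `nrow(X)` rows and `length(t)` columns.
#' @export
censoring_survival <- function(spec, coeffs, t, X) {
  p <- params_at(spec, coeffs, X)
  out <- sapply(t, function(ti)
    1 - margin_cdf(spec$margin_C, ti, p[, 3], p[, 4]))
  matrix(out, nrow = nrow(p))
}

# ---- eta-scale likelihood core (hot path of the boosting engine) ----------
#
# The boosting engine evaluates the loss after a tentative update of a single
# predictor column five times per iteration, so the margin transforms are
# cached and only the pieces touched by the updated column are recomputed.

# fast margin evaluation from predictor-scale parameters; ly = log(y)
.margin_cache <- function(spec, ly, eta_mu, eta_sigma) {
  sigma <- exp(eta_sigma)
  if (spec$family == "weibull") {
    w <- sigma * (ly - eta_mu)
    z <- exp(w)
    S <- exp(-z)
    list(mu = exp(eta_mu), sigma = sigma, F = -expm1(-z),
         logf = eta_sigma - eta_mu + (sigma - 1) * (ly - eta_mu) - z,
         w = w, z = z, S = S)
  } else {
    r <- (ly - eta_mu) / sigma
    list(mu = eta_mu, sigma = sigma, F = stats::pnorm(r),
         logf = -ly - eta_sigma - 0.5 * r * r - 0.918938533204672742,
         r = r)
  }
}

# derivatives on the predictor scale from cached margin quantities
.margin_cache_derivs <- function(spec, mc) {
  if (spec$family == "weibull") {
    list(dlogf_mu    = mc$sigma * (mc$z - 1),
         dlogf_sigma = 1 + mc$w * (1 - mc$z),
         dF_mu       = -mc$sigma * mc$z * mc$S,
         dF_sigma    = mc$z * mc$w * mc$S)
  } else {
    phi <- exp(-0.5 * mc$r * mc$r) * 0.398942280401432678
    list(dlogf_mu    = mc$r / mc$sigma,
         dlogf_sigma = mc$r * mc$r - 1,
         dF_mu       = -phi / mc$sigma,
         dF_sigma    = -phi * mc$r)
  }
}

.copula_cache <- function(spec, eta, y, delta) {
  ly <- log(.clip_pos(y))
  mcT <- .margin_cache(spec$margin_T, ly, eta[, 1], eta[, 2])
  mcC <- .margin_cache(spec$margin_C, ly, eta[, 3], eta[, 4])
  cache <- list(spec = spec, eta = eta, ly = ly, delta = delta,
                ev = delta == 1,
                mcT = mcT, mcC = mcC,
                u = .clip01(mcT$F), v = .clip01(mcC$F),
                theta = copula_link_inv(spec$copula, eta[, 5]))
  if (spec$copula$family == "gaussian") {
    cache$qa <- stats::qnorm(cache$u)
    cache$qb <- stats::qnorm(cache$v)
  }
  cache
}

# update the cache after adding `dcol` to predictor column k
.copula_cache_update <- function(cache, k, dcol) {
  spec <- cache$spec
  eta <- cache$eta
  eta[, k] <- eta[, k] + dcol
  cache$eta <- eta
  if (k <= 2L) {
    cache$mcT <- .margin_cache(spec$margin_T, cache$ly, eta[, 1], eta[, 2])
    cache$u <- .clip01(cache$mcT$F)
    if (spec$copula$family == "gaussian") cache$qa <- stats::qnorm(cache$u)
  } else if (k <= 4L) {
    cache$mcC <- .margin_cache(spec$margin_C, cache$ly, eta[, 3], eta[, 4])
    cache$v <- .clip01(cache$mcC$F)
    if (spec$copula$family == "gaussian") cache$qb <- stats::qnorm(cache$v)
  } else {
    cache$theta <- copula_link_inv(spec$copula, eta[, 5])
  }
  cache
}

# h(v|u) on a row subset, using cached normal quantiles for the gaussian
.cache_h <- function(cache, idx, swap = FALSE) {
  spec <- cache$spec$copula
  th <- cache$theta[idx]
  if (spec$family == "gaussian") {
    a <- if (swap) cache$qb[idx] else cache$qa[idx]
    b <- if (swap) cache$qa[idx] else cache$qb[idx]
    s <- sqrt((1 - th) * (1 + th))
    stats::pnorm((b - th * a) / s)
  } else if (swap) {
    .h_vgu(spec, cache$v[idx], cache$u[idx], th)
  } else {
    .h_vgu(spec, cache$u[idx], cache$v[idx], th)
  }
}

.copula_loglik_cache <- function(cache) {
  ev <- cache$ev
  ll <- numeric(length(ev))
  if (any(ev)) {
    h <- .cache_h(cache, ev)
    ll[ev] <- pmax(cache$mcT$logf[ev], -690) + log(.clip_pos(1 - h, 1e-12))
  }
  if (any(!ev)) {
    h <- .cache_h(cache, !ev, swap = TRUE)
    ll[!ev] <- pmax(cache$mcC$logf[!ev], -690) + log(.clip_pos(1 - h, 1e-12))
  }
  ll
}

.copula_risk_cache <- function(cache) -sum(.copula_loglik_cache(cache))

# per-observation log-likelihood contributions given an n x 5 eta matrix
.copula_loglik_eta <- function(spec, eta, y, delta) {
  .copula_loglik_cache(.copula_cache(spec, eta, y, delta))
}

.copula_risk_eta <- function(spec, eta, y, delta) {
  -sum(.copula_loglik_eta(spec, eta, y, delta))
}

# per-observation score d loglik / d eta_k -> n x 5 matrix
.copula_scores_cache <- function(cache) {
  spec <- cache$spec
  n <- length(cache$ly)
  u <- cache$u; v <- cache$v
  dT <- .margin_cache_derivs(spec$margin_T, cache$mcT)
  dC <- .margin_cache_derivs(spec$margin_C, cache$mcC)
  dth <- .dtheta_deta(spec$copula, cache$theta)
  s <- matrix(0, n, 5, dimnames = list(NULL, .PARAM_NAMES))
  ev <- cache$ev
  if (any(ev)) {
    th <- cache$theta[ev]
    h <- .h_vgu(spec$copula, u[ev], v[ev], th)
    hd <- .h_vgu_derivs(spec$copula, u[ev], v[ev], th)
    # where the 1 - h floor binds, the computed loss is locally flat in the
    # h-term, so its gradient contribution is zero (documented clipping)
    w <- as.numeric(1 - h > 1e-12)
    denom <- .clip_pos(1 - h, 1e-12)
    s[ev, 1] <- dT$dlogf_mu[ev]    - w * hd$du * dT$dF_mu[ev]    / denom
    s[ev, 2] <- dT$dlogf_sigma[ev] - w * hd$du * dT$dF_sigma[ev] / denom
    s[ev, 3] <- -w * hd$dv * dC$dF_mu[ev]    / denom
    s[ev, 4] <- -w * hd$dv * dC$dF_sigma[ev] / denom
    s[ev, 5] <- -w * hd$dtheta * dth[ev] / denom
  }
  if (any(!ev)) {
    th <- cache$theta[!ev]
    # h_{T|C}(u | v) = dC/dv; by exchange symmetry evaluate v_given_u at (v, u)
    h <- .h_vgu(spec$copula, v[!ev], u[!ev], th)
    hd <- .h_vgu_derivs(spec$copula, v[!ev], u[!ev], th)
    w <- as.numeric(1 - h > 1e-12)
    denom <- .clip_pos(1 - h, 1e-12)
    s[!ev, 1] <- -w * hd$dv * dT$dF_mu[!ev]    / denom
    s[!ev, 2] <- -w * hd$dv * dT$dF_sigma[!ev] / denom
    s[!ev, 3] <- dC$dlogf_mu[!ev]    - w * hd$du * dC$dF_mu[!ev]    / denom
    s[!ev, 4] <- dC$dlogf_sigma[!ev] - w * hd$du * dC$dF_sigma[!ev] / denom
    s[!ev, 5] <- -w * hd$dtheta * dth[!ev] / denom
  }
  s
}

.copula_scores_eta <- function(spec, eta, y, delta) {
  .copula_scores_cache(.copula_cache(spec, eta, y, delta))
}

#' Joint negative log-likelihood under dependent censoring
#'
#' Sums `-log` of the delta-appropriate part of [observed_density_Y()] over
#' the sample: events contribute \eqn{f_T (1 - h_{C|T})}, censored rows
#' \eqn{f_C (1 - h_{T|C})}.
#'
#' @inheritParams params_at
#' @param data a [survival_dataset()].
#' @export
neg_loglik <- function(spec, coeffs, data) {
  stopifnot(inherits(data, "survival_dataset"))
  eta <- eval_predictors(coeffs, data$X)
  .copula_risk_eta(spec, eta, data$y, data$delta)
}

#' Per-observation negative gradients on the predictor scale
#'
#' Returns the n x 5 matrix of \eqn{-\partial \ell_i/\partial \eta_k}; the
#' boosting engine fits base-learners to the negation of these columns (the
#' negative gradient of the negative log-likelihood loss).
#'
#' @inheritParams neg_loglik
#' @export
neg_gradients <- function(spec, coeffs, data) {
  stopifnot(inherits(data, "survival_dataset"))
  eta <- eval_predictors(coeffs, data$X)
  -.copula_scores_eta(spec, eta, data$y, data$delta)
}

# ---- independence-censoring AFT loss --------------------------------------

.aft_cache <- function(margin, eta, y, delta) {
  ly <- log(.clip_pos(y))
  list(margin = margin, eta = eta, ly = ly, delta = delta,
       mc = .margin_cache(margin, ly, eta[, 1], eta[, 2]))
}

.aft_cache_update <- function(cache, k, dcol) {
  cache$eta[, k] <- cache$eta[, k] + dcol
  cache$mc <- .margin_cache(cache$margin, cache$ly,
                            cache$eta[, 1], cache$eta[, 2])
  cache
}

.aft_loglik_cache <- function(cache) {
  lf <- pmax(cache$mc$logf, -690)
  ls <- log(.clip_pos(1 - cache$mc$F, 1e-12))
  cache$delta * lf + (1 - cache$delta) * ls
}

.aft_risk_cache <- function(cache) -sum(.aft_loglik_cache(cache))

.aft_scores_cache <- function(cache) {
  d <- .margin_cache_derivs(cache$margin, cache$mc)
  S <- .clip_pos(1 - cache$mc$F, 1e-12)
  delta <- cache$delta
  cbind(mu = delta * d$dlogf_mu + (1 - delta) * (-d$dF_mu / S),
        sigma = delta * d$dlogf_sigma + (1 - delta) * (-d$dF_sigma / S))
}

.aft_loglik_eta <- function(margin, eta, y, delta) {
  .aft_loglik_cache(.aft_cache(margin, eta, y, delta))
}

.aft_risk_eta <- function(margin, eta, y, delta) {
  -sum(.aft_loglik_eta(margin, eta, y, delta))
}

.aft_scores_eta <- function(margin, eta, y, delta) {
  .aft_scores_cache(.aft_cache(margin, eta, y, delta))
}

#' Censored negative log-likelihood of the distributional AFT benchmark
#'
#' The accelerated failure time benchmark treats censoring as independent:
#' \eqn{-\ell = -\sum_i [\delta_i \log f_T(y_i) + (1-\delta_i)\log S_T(y_i)]},
#' with both margin parameters regressed on covariates.
#'
#' @param margin_T a [margin_spec()] for the survival margin.
#' @param coeffs a [predictor_coefficients()] with K = 2 predictors
#'   (mu_T, sigma_T).
#' @param data a [survival_dataset()].
#' @export
aft_neg_loglik <- function(margin_T, coeffs, data) {
  stopifnot(inherits(data, "survival_dataset"))
  eta <- eval_predictors(coeffs, data$X)
  .aft_risk_eta(margin_T, eta, data$y, data$delta)
}

#' @rdname aft_neg_loglik
#' @export
aft_neg_gradients <- function(margin_T, coeffs, data) {
  stopifnot(inherits(data, "survival_dataset"))
  eta <- eval_predictors(coeffs, data$X)
  -.aft_scores_eta(margin_T, eta, data$y, data$delta)
}
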