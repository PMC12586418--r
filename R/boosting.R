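#' Boosting configuration
#'
#' @param nu step length in (0, 1); the fraction of the best-fitting
#'   base-learner added per iteration (default 0.01).
#' @param mstop_max iteration budget (default 5000).
#' @param seed optional seed governing fold partitioning; the boosting path
#'   itself is deterministic given the data.
#' @export
boost_config <- function(nu = 0.01, mstop_max = 5000, seed = NULL) {
  if (!(nu > 0 && nu < 1)) .stopf("'nu' must lie in (0, 1)")
  if (mstop_max < 0) .stopf("'mstop_max' must be >= 0")
  structure(list(nu = nu, mstop_max = as.integer(mstop_max), seed = seed),
            class = "boost_config")
}

# ---- loss families --------------------------------------------------------

.boost_family <- function(spec) {
  if (inherits(spec, "model_spec")) {
    list(type = "copula", spec = spec, K = 5L, names = .PARAM_NAMES,
         risk = function(eta, y, delta) .copula_risk_eta(spec, eta, y, delta),
         scores = function(eta, y, delta) .copula_scores_eta(spec, eta, y, delta),
         new_cache = function(eta, y, delta) .copula_cache(spec, eta, y, delta),
         update = .copula_cache_update,
         risk_c = .copula_risk_cache,
         scores_c = .copula_scores_cache)
  } else if (inherits(spec, "margin_spec")) {
    list(type = "aft", spec = spec, K = 2L, names = c("mu_T", "sigma_T"),
         risk = function(eta, y, delta) .aft_risk_eta(spec, eta, y, delta),
         scores = function(eta, y, delta) .aft_scores_eta(spec, eta, y, delta),
         new_cache = function(eta, y, delta) .aft_cache(spec, eta, y, delta),
         update = .aft_cache_update,
         risk_c = .aft_risk_cache,
         scores_c = .aft_scores_cache)
  } else .stopf("'spec' must be a model_spec (copula model) or margin_spec (AFT)")
}

# crude intercept start for one margin's censored fit
.margin_eta_start <- function(margin, y) {
  if (margin$family == "weibull") c(log(mean(y)), 0) else c(mean(log(y)), 0)
}

#' Intercept-only offsets on the predictor scale
#'
#' Minimizes the model's negative log-likelihood over the predictor
#' intercepts with all covariate effects at zero, started from
#' independence-censoring fits of each margin (and zero on the dependence
#' link).  These offsets initialize every boosting run.
#'
#' @param spec a [model_spec()] (copula model, 5 offsets) or a
#'   [margin_spec()] (AFT benchmark, 2 offsets).
#' @param data a [survival_dataset()].
#' @return named numeric vector of offsets.
#' @export
fit_offsets <- function(spec, data) {
  stopifnot(inherits(data, "survival_dataset"))
  fam <- .boost_family(spec)
  y <- data$y; delta <- data$delta; n <- length(y)
  obj <- function(par) fam$risk(matrix(par, n, fam$K, byrow = TRUE), y, delta)
  grad <- function(par)
    -colSums(fam$scores(matrix(par, n, fam$K, byrow = TRUE), y, delta))
  start <- .stagewise_offsets(spec, y, delta)
  fit <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0)
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000))
  if (fit$convergence != 0)
    .stopf("offset optimization failed to converge (code %d, value %g)",
           fit$convergence, fit$value)
  stats::setNames(fit$par, fam$names)
}

.aft_intercept_fit <- function(margin, y, delta) {
  n <- length(y)
  obj <- function(par)
    .aft_risk_eta(margin, matrix(par, n, 2, byrow = TRUE), y, delta)
  fit <- stats::optim(.margin_eta_start(margin, y), obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  fit$par
}

# stagewise initialization: independence-censoring fit of each margin, then a
# univariate search for the dependence offset with the margins held fixed.
# The joint intercept-only optimum can sit in a degenerate near-comonotone
# basin (both margins dragged onto each other, |dependence| -> 1) that traps
# the non-cyclic boosting path, so boosting starts here instead.
.stagewise_offsets <- function(spec, y, delta) {
  fam <- .boost_family(spec)
  if (fam$type == "aft") return(stats::setNames(.aft_intercept_fit(spec, y, delta),
                                                fam$names))
  n <- length(y)
  sT <- .aft_intercept_fit(spec$margin_T, y, delta)
  sC <- .aft_intercept_fit(spec$margin_C, y, 1 - delta)
  ro <- stats::optimize(function(r)
    .copula_risk_eta(spec, matrix(c(sT, sC, r), n, 5, byrow = TRUE), y, delta),
    c(-5, 5))$minimum
  stats::setNames(c(sT, sC, ro), fam$names)
}

#' Least-squares base-learner
#'
#' Fits the no-intercept least-squares slope of a gradient vector on one
#' centered covariate.  Returns the slope and the residual sum of squares used
#' as the within-parameter selection criterion.
#'
#' @param gradient numeric response vector.
#' @param covariate centered covariate vector of the same length.
#' @export
base_learner_fit <- function(gradient, covariate) {
  ss <- sum(covariate^2)
  if (ss <= 0) return(list(coefficient = 0, rss = Inf))
  b <- sum(gradient * covariate) / ss
  list(coefficient = b, rss = sum(gradient^2) - b^2 * ss)
}

# ---- engine state ---------------------------------------------------------

#' Initialize a boosting state
#'
#' Builds the mutable state consumed by [boost_iteration()]: centered
#' covariates, offsets, current predictor matrix and empty paths.  Used
#' internally by [fit_boost()].
#'
#' @inheritParams fit_offsets
#' @param config a [boost_config()].
#' @param data_val optional validation [survival_dataset()] with the same
#'   covariates.
#' @export
boost_init <- function(spec, data, config, data_val = NULL) {
  stopifnot(inherits(config, "boost_config"))
  fam <- .boost_family(spec)
  X <- data$X
  p <- ncol(X)
  centers <- if (p > 0) colMeans(X) else numeric(0)
  Xc <- if (p > 0) sweep(X, 2, centers) else X
  ssx <- if (p > 0) colSums(Xc^2) else numeric(0)
  offsets <- .stagewise_offsets(spec, data$y, data$delta)
  n <- length(data$y)
  eta <- matrix(offsets, n, fam$K, byrow = TRUE,
                dimnames = list(NULL, fam$names))
  cache <- fam$new_cache(eta, data$y, data$delta)
  state <- list(fam = fam, config = config,
                n = n, Xc = Xc, ssx = ssx,
                centers = centers, p = p, names = colnames(X),
                offsets = offsets, cache = cache,
                beta = matrix(0, p, fam$K), b0 = numeric(fam$K),
                m = 0L,
                trace_param = integer(config$mstop_max),
                trace_learner = integer(config$mstop_max),
                trace_inc = numeric(config$mstop_max),
                risk_train = numeric(config$mstop_max),
                risk0 = fam$risk_c(cache))
  if (!is.null(data_val)) {
    stopifnot(inherits(data_val, "survival_dataset"))
    if (ncol(data_val$X) != p)
      .stopf("validation covariate matrix has %d columns, expected %d",
             ncol(data_val$X), p)
    state$Xv <- if (p > 0) sweep(data_val$X, 2, centers) else data_val$X
    eta_val <- matrix(offsets, length(data_val$y), fam$K, byrow = TRUE)
    state$cache_val <- fam$new_cache(eta_val, data_val$y, data_val$delta)
    state$risk_val <- numeric(config$mstop_max)
    state$risk0_val <- fam$risk_c(state$cache_val)
  }
  state
}

#' One non-cyclic boosting iteration
#'
#' Computes all per-parameter negative gradients, fits every base-learner
#' (each centered covariate plus an intercept learner) to each gradient
#' column, selects the best learner per parameter by residual sum of squares,
#' then compares the parameters by the actual empirical risk after a
#' tentative `nu`-scaled update and commits the single best update.
#' Tie-breaking is deterministic: lowest parameter index, then lowest
#' covariate index, intercept last.
#'
#' @param state a state from [boost_init()].
#' @return the updated state (exactly one trace entry appended).
#' @export
boost_iteration <- function(state) {
  fam <- state$fam
  K <- fam$K; p <- state$p
  nu <- state$config$nu
  n <- state$n
  g <- fam$scores_c(state$cache)             # d loglik / d eta, n x K
  if (p > 0) {
    num <- crossprod(state$Xc, g)            # p x K
    slopes <- num / state$ssx
    rss_x <- rep(colSums(g^2), each = p) - slopes^2 * state$ssx
    dim(rss_x) <- c(p, K)
  }
  gbar <- colMeans(g)
  rss_int <- colSums(g^2) - n * gbar^2
  best_j <- integer(K); best_coef <- numeric(K); risk_k <- rep(Inf, K)
  cand <- vector("list", K)
  for (k in seq_len(K)) {
    if (p > 0) {
      rss_k <- c(rss_x[, k], rss_int[k])     # intercept last (tie-break)
      j <- which.min(rss_k)
    } else j <- 1L
    if (p > 0 && j <= p) {
      best_j[k] <- j
      best_coef[k] <- slopes[j, k]
      upd <- nu * best_coef[k] * state$Xc[, j]
    } else {
      best_j[k] <- 0L                        # intercept learner
      best_coef[k] <- gbar[k]
      upd <- rep(nu * best_coef[k], n)
    }
    cand[[k]] <- fam$update(state$cache, k, upd)
    risk_k[k] <- fam$risk_c(cand[[k]])
  }
  k_star <- which.min(risk_k)                # ties: lowest parameter index
  m <- state$m + 1L
  if (!is.finite(risk_k[k_star]))
    .stopf("non-finite risk at boosting iteration %d", m)
  inc <- nu * best_coef[k_star]
  state$cache <- cand[[k_star]]
  if (best_j[k_star] == 0L) {
    state$b0[k_star] <- state$b0[k_star] + inc
  } else {
    state$beta[best_j[k_star], k_star] <- state$beta[best_j[k_star], k_star] + inc
  }
  state$trace_param[m] <- k_star
  state$trace_learner[m] <- best_j[k_star]
  state$trace_inc[m] <- inc
  state$risk_train[m] <- risk_k[k_star]
  if (!is.null(state$cache_val)) {
    upd_v <- if (best_j[k_star] == 0L) rep(inc, nrow(state$Xv))
             else inc * state$Xv[, best_j[k_star]]
    state$cache_val <- fam$update(state$cache_val, k_star, upd_v)
    state$risk_val[m] <- fam$risk_c(state$cache_val)
  }
  state$m <- m
  state
}

#' Fit a boosted distributional model
#'
#' Runs `mstop_max` non-cyclic boosting iterations for either the joint
#' copula model (`spec` a [model_spec()]; 5 additive predictors) or the
#' independence-censoring AFT benchmark (`spec` a [margin_spec()]; 2
#' predictors).  When a validation set is supplied, the stopping iteration
#' `m_stop` is the (first) minimizer of the validation risk path over
#' iterations `0..mstop_max`; otherwise `m_stop = mstop_max`.  Covariates
#' never selected keep exactly zero coefficients.
#'
#' @inheritParams boost_init
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (the reference
#'   implementation built on [boost_init()]/[boost_iteration()]); both produce
#'   identical paths.
#' @return an object of class `boost_fit`.
#' @export
fit_boost <- function(spec, data, config = boost_config(), data_val = NULL,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "r") return(.fit_boost_r(spec, data, config, data_val))
  stopifnot(inherits(config, "boost_config"), inherits(data, "survival_dataset"))
  fam <- .boost_family(spec)
  X <- data$X; p <- ncol(X)
  centers <- if (p > 0) colMeans(X) else numeric(0)
  Xc <- if (p > 0) sweep(X, 2, centers) else X
  ssx <- if (p > 0) colSums(Xc^2) else numeric(0)
  offsets <- .stagewise_offsets(spec, data$y, data$delta)
  is_aft <- fam$type == "aft"
  mcode <- function(m) if (m$family == "weibull") 0L else 1L
  ccode <- if (is_aft) 0L else
    match(fam$spec$copula$family, c("clayton", "gaussian", "gumbel")) - 1L
  Xv <- NULL; yv <- NULL; dv <- NULL
  if (!is.null(data_val)) {
    stopifnot(inherits(data_val, "survival_dataset"))
    if (ncol(data_val$X) != p)
      .stopf("validation covariate matrix has %d columns, expected %d",
             ncol(data_val$X), p)
    Xv <- if (p > 0) sweep(data_val$X, 2, centers) else data_val$X
    yv <- data_val$y; dv <- as.integer(data_val$delta)
  }
  res <- .cpp_boost_engine(data$y, as.integer(data$delta), Xc, ssx,
                           unname(offsets), config$nu, config$mstop_max,
                           if (is_aft) mcode(spec) else mcode(spec$margin_T),
                           if (is_aft) 0L else mcode(spec$margin_C),
                           ccode, is_aft, yv, dv, Xv)
  M <- config$mstop_max
  risk_val <- NULL; mstop <- M
  if (!is.null(data_val)) {
    risk_val <- c(res$risk0_val, res$risk_val)
    mstop <- which.min(risk_val) - 1L
  }
  structure(list(
    type = fam$type, spec = spec,
    param_names = fam$names,
    offsets = offsets, centers = centers,
    covariate_names = colnames(X),
    nu = config$nu, mstop_max = M, mstop = mstop,
    trace = data.frame(iteration = seq_len(M),
                       param = res$trace_param,
                       learner = res$trace_learner,
                       increment = res$trace_inc),
    risk_train = c(res$risk0, res$risk_train),
    risk_val = risk_val),
    class = "boost_fit")
}

.fit_boost_r <- function(spec, data, config, data_val = NULL) {
  state <- boost_init(spec, data, config, data_val)
  for (m in seq_len(config$mstop_max)) state <- boost_iteration(state)
  M <- state$m
  risk_val <- NULL; mstop <- M
  if (!is.null(state$cache_val)) {
    risk_val <- c(state$risk0_val, state$risk_val[seq_len(M)])
    mstop <- which.min(risk_val) - 1L
  }
  structure(list(
    type = state$fam$type, spec = spec,
    param_names = state$fam$names,
    offsets = state$offsets, centers = state$centers,
    covariate_names = state$names,
    nu = config$nu, mstop_max = M, mstop = mstop,
    trace = data.frame(iteration = seq_len(M),
                       param = state$trace_param[seq_len(M)],
                       learner = state$trace_learner[seq_len(M)],
                       increment = state$trace_inc[seq_len(M)]),
    risk_train = c(state$risk0, state$risk_train[seq_len(M)]),
    risk_val = risk_val),
    class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  cat(sprintf("<boost_fit> %s model, %d iterations run, m_stop = %d\n",
              x$type, x$mstop_max, x$mstop))
  cat(sprintf("  risk: %.4f (offset) -> %.4f (m_stop)\n",
              x$risk_train[1], x$risk_train[x$mstop + 1]))
  invisible(x)
}

#' Coefficients of a boosted fit at a given iteration
#'
#' Reconstructs the additive-predictor coefficients by replaying the update
#' trace up to `at_iteration` (default: the selected `m_stop`).
#'
#' @param object a `boost_fit`.
#' @param at_iteration iteration in `0..mstop_max`.
#' @param ... unused.
#' @return a [predictor_coefficients()] object; intercepts include offsets.
#' @export
coef.boost_fit <- function(object, at_iteration = NULL, ...) {
  m <- if (is.null(at_iteration)) object$mstop else as.integer(at_iteration)
  if (m < 0 || m > object$mstop_max)
    .stopf("'at_iteration' must lie in 0..%d", object$mstop_max)
  K <- length(object$offsets)
  p <- length(object$centers)
  beta <- matrix(0, p, K)
  b0 <- numeric(K)
  if (m > 0) {
    tr <- object$trace[seq_len(m), , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      if (tr$learner[i] == 0L)
        b0[tr$param[i]] <- b0[tr$param[i]] + tr$increment[i]
      else
        beta[tr$learner[i], tr$param[i]] <-
          beta[tr$learner[i], tr$param[i]] + tr$increment[i]
    }
  }
  rownames(beta) <- object$covariate_names
  predictor_coefficients(object$offsets + b0, beta, object$centers,
                         object$param_names)
}

#' Predict from a boosted fit
#'
#' @param object a `boost_fit`.
#' @param X_new covariate matrix.
#' @param at_iteration iteration to predict at (default `m_stop`).
#' @param type `"parameters"` for natural-scale distribution parameters,
#'   `"survival"` for \eqn{\hat S_T(t|x)}, `"censor_survival"` for
#'   \eqn{\hat G(t|x)} (copula fits only).
#' @param times time grid for the survival types.
#' @param ... unused.
#' @export
predict.boost_fit <- function(object, X_new, at_iteration = NULL,
                              type = c("parameters", "survival",
                                       "censor_survival"),
                              times = NULL, ...) {
  type <- match.arg(type)
  X_new <- as.matrix(X_new)
  cf <- coef.boost_fit(object, at_iteration)
  eta <- eval_predictors(cf, X_new)
  if (object$type == "aft") {
    par <- .margin_link_inv(object$spec, eta[, 1], eta[, 2])
    params <- cbind(mu_T = par$mu, sigma_T = par$sigma)
    if (type == "parameters") return(params)
    if (type == "censor_survival")
      .stopf("censor_survival predictions require a copula fit")
    margin <- object$spec
    mu <- par$mu; sigma <- par$sigma
  } else {
    params <- .params_from_eta(object$spec, eta)
    if (type == "parameters") return(params)
    if (type == "survival") {
      margin <- object$spec$margin_T
      mu <- params[, 1]; sigma <- params[, 2]
    } else {
      margin <- object$spec$margin_C
      mu <- params[, 3]; sigma <- params[, 4]
    }
  }
  if (is.null(times)) .stopf("'times' is required for survival predictions")
  out <- vapply(times, function(t) 1 - margin_cdf(margin, t, mu, sigma),
                numeric(nrow(X_new)))
  matrix(out, nrow = nrow(X_new),
         dimnames = list(NULL, paste0("t", seq_along(times))))
}

# ---- cross-validation -----------------------------------------------------

.make_folds <- function(n, folds, seed) {
  if (folds < 2) .stopf("'folds' must be at least 2")
  if (folds > n) .stopf("more folds than observations")
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

.subset_data <- function(data, idx) {
  survival_dataset(data$y[idx], data$delta[idx],
                   data$X[idx, , drop = FALSE], data$names)
}

#' Cross-validated stopping iteration
#'
#' For each fold, fits on the remaining folds while tracking the held-out
#' risk path; `m_stop` is the minimizer of the fold-averaged held-out risk
#' over `0..mstop_max`.
#'
#' @inheritParams boost_init
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold partition.
#' @export
cv_stop <- function(spec, data, config, folds = 10, seed = 1) {
  fold_id <- .make_folds(length(data$y), folds, seed)
  paths <- sapply(seq_len(folds), function(f) {
    fit <- fit_boost(spec, .subset_data(data, fold_id != f), config,
                     data_val = .subset_data(data, fold_id == f))
    fit$risk_val
  })
  mean_path <- rowMeans(paths)
  structure(which.min(mean_path) - 1L, risk_path = mean_path)
}

#' Cross-validated predictive log-likelihood model selection
#'
#' Scores candidate model specifications by the summed held-out
#' log-likelihood over a seeded k-fold partition.  Within each fold, 25% of
#' the training part is split off as a validation set to select that fold's
#' `m_stop`; the untouched held-out fold is then scored at the selected
#' iteration.  Higher scores are better.
#'
#' @param specs named list of [model_spec()] candidates.
#' @inheritParams cv_stop
#' @return a `data.frame` with one row per spec, ranked by score.
#' @export
cv_predictive_loglik <- function(specs, data, config, folds = 10, seed = 1) {
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s)
      paste(s$margin_T$family, s$copula$family, sep = "+"), "")
  n <- length(data$y)
  fold_id <- .make_folds(n, folds, seed)
  if (!is.null(seed)) set.seed(seed + 1L)
  val_pick <- stats::runif(n)   # shared inner-split draws across specs
  scores <- vapply(specs, function(sp) {
    total <- 0
    for (f in seq_len(folds)) {
      tr_idx <- which(fold_id != f)
      inner_val <- val_pick[tr_idx] < 0.25
      if (sum(inner_val) < 2 || sum(!inner_val) < 2)
        .stopf("fold %d too small for an inner validation split", f)
      fit <- fit_boost(sp, .subset_data(data, tr_idx[!inner_val]), config,
                       data_val = .subset_data(data, tr_idx[inner_val]))
      heldout <- .subset_data(data, which(fold_id == f))
      total <- total - neg_loglik(sp, coef(fit), heldout)
    }
    total
  }, numeric(1))
  out <- data.frame(model = names(specs), score = scores,
                    row.names = NULL)
  out[order(-out$score), ]
}
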