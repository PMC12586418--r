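# small Setting-1-style world shared across boosting tests
boost_world <- local({
  st <- simulation_setting(1, "weibull", "gaussian", censoring = 20,
                           p_per_parameter = 5, n = 400, seed = 42)
  rep <- simulate_replicate(st, n_val = 400)
  list(spec = model_spec(margin_spec("weibull"), margin_spec("weibull"),
                         copula_spec("gaussian")),
       train = rep$train$data, val = rep$val$data)
})

test_that("base_learner_fit is the closed-form least-squares slope", {
  set.seed(1)
  x <- rnorm(50); x <- x - mean(x)
  fit <- base_learner_fit(x, x)
  expect_equal(fit$coefficient, 1)
  expect_equal(fit$rss, 0, tolerance = 1e-10)
  g <- rnorm(50)
  g_orth <- g - x * sum(g * x) / sum(x^2)
  expect_equal(base_learner_fit(g_orth, x)$coefficient, 0, tolerance = 1e-12)
  expect_equal(base_learner_fit(g, x)$coefficient, sum(g * x) / sum(x^2))
  expect_equal(base_learner_fit(g, rep(0, 50))$rss, Inf)
})

test_that("fit_offsets recovers true intercepts on effect-free data", {
  # intercept-only truth: dependent censoring but no covariate effects.
  # The dependence link is weakly identified from (Y, delta) alone, so the
  # recovery check runs at n = 50000 where the MLE is inside +/- 0.05.
  gen <- function(n, seed) {
    set.seed(seed)
    spec <- boost_world$spec
    uv <- sample_pair(spec$copula, rep(tanh(0.8), n))
    T_lat <- margin_quantile(spec$margin_T, uv[, 1], exp(0.3), exp(0.2))
    C_lat <- margin_quantile(spec$margin_C, uv[, 2], exp(0.5), exp(-0.1))
    survival_dataset(pmin(T_lat, C_lat), as.numeric(T_lat <= C_lat),
                     matrix(runif(n), n, 1))
  }
  spec <- boost_world$spec
  big <- gen(50000, 9)
  expect_equal(unname(fit_offsets(spec, big)),
               c(0.3, 0.2, 0.5, -0.1, 0.8), tolerance = 0.05)
  d <- gen(2000, 10)
  off <- fit_offsets(spec, d)
  # score identity at the joint offsets
  cf <- predictor_coefficients(off, matrix(0, 1, 5), 0)
  expect_lt(max(abs(colMeans(neg_gradients(spec, cf, d)))), 1e-4)
  # invariant to row permutation
  idx <- sample(2000)
  dperm <- survival_dataset(d$y[idx], d$delta[idx], d$X[idx, , drop = FALSE])
  expect_equal(fit_offsets(spec, dperm), off, tolerance = 1e-6)
})

test_that("boost_iteration commits exactly the exhaustive-search winner", {
  cfg <- boost_config(nu = 0.1, mstop_max = 12)
  d <- boost_world$train
  state <- boost_init(boost_world$spec, d, cfg)
  fam <- copboost:::.boost_family(boost_world$spec)
  centers <- colMeans(d$X)
  Xc <- sweep(d$X, 2, centers)
  for (it in 1:12) {
    # brute-force oracle: every (parameter, learner) candidate evaluated
    # from scratch through the public loss
    eta_now <- state$cache$eta
    g <- fam$scores(eta_now, d$y, d$delta)
    best <- list(risk = Inf)
    for (k in 1:5) {
      cands <- lapply(seq_len(ncol(Xc)), function(j) {
        b <- sum(g[, k] * Xc[, j]) / sum(Xc[, j]^2)
        list(j = j, coef = b, rss = sum((g[, k] - b * Xc[, j])^2))
      })
      cands[[length(cands) + 1]] <- list(j = 0L, coef = mean(g[, k]),
                                         rss = sum((g[, k] - mean(g[, k]))^2))
      pick <- cands[[which.min(vapply(cands, `[[`, 0, "rss"))]]
      eta_try <- eta_now
      upd <- if (pick$j == 0) rep(cfg$nu * pick$coef, nrow(eta_try))
             else cfg$nu * pick$coef * Xc[, pick$j]
      eta_try[, k] <- eta_try[, k] + upd
      risk <- fam$risk(eta_try, d$y, d$delta)
      if (risk < best$risk) best <- list(risk = risk, k = k, j = pick$j)
    }
    m_before <- state$m
    state <- boost_iteration(state)
    expect_equal(state$m, m_before + 1L)
    expect_equal(state$trace_param[state$m], best$k)
    expect_equal(state$trace_learner[state$m], best$j)
    expect_equal(state$risk_train[state$m], best$risk, tolerance = 1e-10)
  }
})

test_that("fit_boost contracts: risk path, m_stop, sparsity, replay", {
  cfg <- boost_config(nu = 0.05, mstop_max = 120)
  fit <- fit_boost(boost_world$spec, boost_world$train, cfg,
                   data_val = boost_world$val)
  expect_true(all(diff(fit$risk_train) <= 1e-9))
  expect_lte(fit$risk_val[fit$mstop + 1], fit$risk_val[1])
  expect_equal(fit$mstop, which.min(fit$risk_val) - 1L)
  # covariates never in the trace have exactly zero coefficients
  cf <- coef(fit, at_iteration = fit$mstop_max)
  never <- setdiff(seq_len(5), fit$trace$learner)
  for (j in never) expect_true(all(cf$beta[j, ] == 0))
  # trace replay reconstructs the increments exactly
  for (k in 1:5) {
    mask <- fit$trace$param == k & fit$trace$learner > 0
    agg <- tapply(fit$trace$increment[mask], fit$trace$learner[mask], sum)
    for (j in names(agg))
      expect_equal(cf$beta[as.integer(j), k], unname(agg[[j]]),
                   tolerance = 1e-12)
  }
  # R and compiled engines produce the same path
  fit_r <- fit_boost(boost_world$spec, boost_world$train, cfg,
                     data_val = boost_world$val, engine = "r")
  expect_equal(fit_r$trace, fit$trace, tolerance = 1e-10)
  expect_equal(fit_r$risk_val, fit$risk_val, tolerance = 1e-8)
})

test_that("predictions are consistent with the coefficient reconstruction", {
  cfg <- boost_config(nu = 0.05, mstop_max = 60)
  fit <- fit_boost(boost_world$spec, boost_world$train, cfg)
  Xn <- boost_world$val$X[1:20, ]
  # iteration 0: offsets only, identical across rows
  p0 <- predict(fit, Xn, at_iteration = 0)
  expect_equal(unname(p0[, "mu_T"]), rep(exp(fit$offsets[["mu_T"]]), 20))
  expect_lt(max(apply(p0, 2, function(x) diff(range(x)))), 1e-12)
  # m = mstop_max equals params_at of the replayed coefficients
  pm <- predict(fit, Xn, at_iteration = fit$mstop_max)
  expect_equal(pm, params_at(fit$spec, coef(fit, fit$mstop_max), Xn),
               tolerance = 1e-12)
  # survival predictions are monotone in t
  S <- predict(fit, Xn, type = "survival", times = seq(0.05, 10, length = 50))
  expect_true(all(apply(S, 1, function(r) all(diff(r) <= 0))))
  G <- predict(fit, Xn, type = "censor_survival",
               times = seq(0.05, 10, length = 50))
  expect_true(all(G >= 0 & G <= 1))
  # mstop_max = 0 degenerates to the offsets
  fit0 <- fit_boost(boost_world$spec, boost_world$train,
                    boost_config(mstop_max = 0))
  expect_equal(predict(fit0, Xn), p0, tolerance = 1e-10)
})

test_that("AFT boosting honours the same engine contracts", {
  cfg <- boost_config(nu = 0.05, mstop_max = 150)
  fit <- fit_boost(margin_spec("weibull"), boost_world$train, cfg,
                   data_val = boost_world$val)
  expect_equal(fit$type, "aft")
  expect_true(all(diff(fit$risk_train) <= 1e-9))
  expect_lte(fit$risk_val[fit$mstop + 1], fit$risk_val[1])
  # x1 (true effect 2 on mu_T) must dominate the selections
  expect_gt(coef(fit)$beta["x1", "mu_T"], 0.5)
  expect_error(predict(fit, boost_world$val$X[1:2, ],
                       type = "censor_survival", times = 1),
               "copula")
})

test_that("noise covariates stay unselected as the noise pool grows", {
  # qualitative sparsity property: the false-positive fraction of the noise
  # pool stays small when the number of available covariates triples
  sp <- boost_world$spec
  for (pk in c(10, 30)) {
    st <- simulation_setting(1, "weibull", "gaussian", censoring = 20,
                             p_per_parameter = pk, n = 600, seed = 314)
    rp <- simulate_replicate(st, n_val = 600)
    fit <- fit_boost(sp, rp$train$data, boost_config(nu = 0.01,
                                                     mstop_max = 2000),
                     data_val = rp$val$data)
    cf <- coef(fit)
    frac_fp <- mean(cf$beta[-(1:5), ] != 0)
    expect_lt(frac_fp, 0.15)
  }
})

test_that("cross-validation utilities are seeded and guarded", {
  d <- boost_world$train
  cfg <- boost_config(nu = 0.1, mstop_max = 25)
  expect_error(cv_stop(boost_world$spec, d, cfg, folds = 1), "at least 2")
  ms1 <- cv_stop(margin_spec("weibull"), d, cfg, folds = 3, seed = 5)
  ms2 <- cv_stop(margin_spec("weibull"), d, cfg, folds = 3, seed = 5)
  expect_identical(as.integer(ms1), as.integer(ms2))
  expect_true(ms1 >= 0 && ms1 <= 25)
  sp <- boost_world$spec
  sc <- cv_predictive_loglik(list(a = sp, b = sp), d, cfg, folds = 2, seed = 3)
  expect_equal(sc$score[1], sc$score[2])  # identical specs, identical folds
  expect_equal(nrow(sc), 2)
})
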