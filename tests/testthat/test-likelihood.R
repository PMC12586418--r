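test_that("survival_dataset validates its invariants", {
  X <- matrix(1:6, 3, 2)
  d <- survival_dataset(c(1, 2, 3), c(1, 0, 1), X)
  expect_s3_class(d, "survival_dataset")
  expect_equal(d$names, c("x1", "x2"))
  expect_error(survival_dataset(c(1, 0, 3), c(1, 0, 1), X), "row 2")
  expect_error(survival_dataset(c(1, 2, 3), c(1, 2, 1), X), "delta")
  expect_error(survival_dataset(c(1, 2), c(1, 0), X), "rows")
  expect_error(survival_dataset(numeric(0), numeric(0),
                                matrix(0, 0, 2)), "at least one")
})

test_that("params_at maps predictors through the links", {
  sp <- model_spec(margin_spec("weibull"), margin_spec("weibull"),
                   copula_spec("gaussian"))
  X <- matrix(runif(20, -1, 1), 10, 2)
  cf0 <- predictor_coefficients(rep(0, 5), matrix(0, 2, 5), colMeans(X))
  p0 <- params_at(sp, cf0, X)
  expect_equal(unname(p0[, "theta"]), rep(0, 10))       # tanh(0)
  expect_equal(unname(p0[, "mu_T"]), rep(1, 10))        # exp(0)
  # Setting-1-style dependence predictor at x5 = 1: theta_clayton = e^3.5
  spc <- model_spec(margin_spec("weibull"), margin_spec("weibull"),
                    copula_spec("clayton"))
  cf <- predictor_coefficients(c(0, 0, 0, 0, 2),
                               matrix(c(rep(0, 9), 1.5), 2, 5), c(0, 0))
  expect_equal(unname(params_at(spc, cf, matrix(c(0, 1), 1))[, "theta"]),
               exp(3.5))
  # link round trip reproduces eta
  set.seed(2)
  cfr <- predictor_coefficients(rnorm(5), matrix(rnorm(10), 2, 5), colMeans(X))
  p <- params_at(sp, cfr, X)
  eta <- copboost:::eval_predictors(cfr, X)
  expect_equal(log(p[, "mu_T"]), eta[, "mu_T"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(atanh(p[, "theta"]), eta[, "rho"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("observed-data CDF and density obey the copula decomposition", {
  y <- seq(0.1, 8, length.out = 60)
  pars <- cbind(mu_T = 1, sigma_T = 1.5, mu_C = 1.2, sigma_C = 1, theta = 2)
  spg <- model_spec(margin_spec("weibull"), margin_spec("weibull"),
                    copula_spec("gaussian"))
  # independence: F_Y = F_T + F_C - F_T F_C and event part f_T (1 - F_C)
  pars0 <- pars; pars0[, "theta"] <- 0
  FT <- margin_cdf(spg$margin_T, y, 1, 1.5)
  FC <- margin_cdf(spg$margin_C, y, 1.2, 1)
  expect_equal(observed_cdf_Y(spg, pars0[rep(1, 60), ], y),
               FT + FC - FT * FC, tolerance = 1e-7)
  expect_equal(observed_density_Y(spg, pars0[rep(1, 60), ], y, "event"),
               margin_pdf(spg$margin_T, y, 1, 1.5) * (1 - FC),
               tolerance = 1e-9)
  expect_equal(observed_cdf_Y(spg, pars0, 1e8), 1, tolerance = 1e-8)
  spc <- model_spec(margin_spec("weibull"), margin_spec("weibull"),
                    copula_spec("clayton"))
  P <- pars[rep(1, 60), ]
  # additivity of the two likelihood parts
  expect_equal(observed_density_Y(spc, P, y, "event") +
                 observed_density_Y(spc, P, y, "censored"),
               observed_density_Y(spc, P, y, "both"), tolerance = 1e-12)
  # F_Y' = f_Y by finite differences
  eps <- 1e-5
  fd <- (observed_cdf_Y(spc, P, y + eps) -
           observed_cdf_Y(spc, P, y - eps)) / (2 * eps)
  expect_rel_equal(observed_density_Y(spc, P, y, "both"), fd, 1e-4)
})

test_that("f_Y integrates to one across copula and margin families", {
  set.seed(4)
  for (mf in ALL_MARGINS) for (cf in ALL_COPULAS) {
    sp <- model_spec(margin_spec(mf), margin_spec(mf), copula_spec(cf))
    pars <- cbind(mu_T = if (mf == "weibull") 1.3 else 0.2, sigma_T = 1.4,
                  mu_C = if (mf == "weibull") 0.8 else -0.1, sigma_C = 0.9,
                  theta = rand_theta(cf, 1))
    total <- integrate(function(t)
      observed_density_Y(sp, pars[rep(1, length(t)), , drop = FALSE], t,
                         "both"),
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("neg_loglik composes the delta-appropriate density parts", {
  pr <- make_random_problem("weibull", "gaussian", n = 30, seed = 21)
  # manual composition from density parts
  P <- params_at(pr$spec, pr$coeffs, pr$data$X)
  part <- ifelse(pr$data$delta == 1, "event", "censored")
  ll <- vapply(seq_len(30), function(i)
    log(observed_density_Y(pr$spec, P[i, , drop = FALSE], pr$data$y[i],
                           part[i])), numeric(1))
  expect_equal(neg_loglik(pr$spec, pr$coeffs, pr$data), -sum(ll),
               tolerance = 1e-10)
  # independence reduction: all events
  d1 <- survival_dataset(pr$data$y, rep(1, 30), pr$data$X)
  cf0 <- pr$coeffs; cf0$intercepts["rho"] <- 0
  cf0$beta[, 5] <- 0
  P0 <- params_at(pr$spec, cf0, pr$data$X)
  # the guarded loss floors 1 - F at 1e-12; mirror that in the oracle
  expect_equal(neg_loglik(pr$spec, cf0, d1),
               -sum(log(margin_pdf(pr$spec$margin_T, d1$y, P0[, 1], P0[, 2])) +
                      log(pmax(1 - margin_cdf(pr$spec$margin_C, d1$y,
                                              P0[, 3], P0[, 4]), 1e-12))),
               tolerance = 1e-7)
  # permutation invariance
  idx <- sample(30)
  dperm <- survival_dataset(pr$data$y[idx], pr$data$delta[idx],
                            pr$data$X[idx, ])
  expect_equal(neg_loglik(pr$spec, pr$coeffs, dperm),
               neg_loglik(pr$spec, pr$coeffs, pr$data), tolerance = 1e-10)
  expect_error(neg_loglik(pr$spec, pr$coeffs, list(y = numeric(0))))
})

test_that("neg_gradients matches the finite-difference oracle everywhere", {
  sd <- 30
  for (mf in ALL_MARGINS) for (cf in ALL_COPULAS) {
    sd <- sd + 1
    pr <- make_random_problem(mf, cf, n = 20, seed = sd)
    g <- neg_gradients(pr$spec, pr$coeffs, pr$data)
    fd <- fd_neg_gradients(pr$spec, pr$coeffs, pr$data)
    expect_rel_equal(g, fd, 1e-5)
  }
})

test_that("independence factorization splits the margin scores", {
  pr <- make_random_problem("lognormal", "gaussian", n = 25, seed = 51)
  cf <- pr$coeffs; cf$intercepts["rho"] <- 0; cf$beta[, 5] <- 0
  g <- neg_gradients(pr$spec, cf, pr$data)
  # T-margin columns equal the censored AFT scores with delta as-is
  cfT <- predictor_coefficients(cf$intercepts[1:2], cf$beta[, 1:2],
                                cf$centers, c("mu_T", "sigma_T"))
  gT <- aft_neg_gradients(pr$spec$margin_T, cfT, pr$data)
  expect_equal(unname(g[, 1:2]), unname(gT), tolerance = 1e-9)
  # C-margin columns equal the AFT scores with the roles of delta flipped
  dC <- survival_dataset(pr$data$y, 1 - pr$data$delta, pr$data$X)
  cfC <- predictor_coefficients(cf$intercepts[3:4], cf$beta[, 3:4],
                                cf$centers, c("mu_T", "sigma_T"))
  gC <- aft_neg_gradients(pr$spec$margin_C, cfC, dC)
  expect_equal(unname(g[, 3:4]), unname(gC), tolerance = 1e-9)
})

test_that("AFT loss reduces correctly and its gradients check out", {
  set.seed(77)
  n <- 25
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  y <- exp(rnorm(n))
  cf <- predictor_coefficients(c(0.3, -0.1), matrix(rnorm(4, sd = 0.4), 2, 2),
                               colMeans(X), c("mu_T", "sigma_T"))
  for (mf in ALL_MARGINS) {
    ms <- margin_spec(mf)
    d1 <- survival_dataset(y, rep(1, n), X)
    d0 <- survival_dataset(y, rep(0, n), X)
    eta <- copboost:::eval_predictors(cf, X)
    par <- copboost:::.margin_link_inv(ms, eta[, 1], eta[, 2])
    expect_equal(aft_neg_loglik(ms, cf, d1),
                 -sum(log(margin_pdf(ms, y, par$mu, par$sigma))),
                 tolerance = 1e-9)
    expect_equal(aft_neg_loglik(ms, cf, d0),
                 -sum(log(pmax(1 - margin_cdf(ms, y, par$mu, par$sigma),
                               1e-12))),
                 tolerance = 1e-9)
    dmix <- survival_dataset(y, rbinom(n, 1, 0.5), X)
    expect_rel_equal(aft_neg_gradients(ms, cf, dmix),
                     fd_aft_neg_gradients(ms, cf, dmix), 1e-5)
  }
})

test_that("censoring survival is a proper conditional survival function", {
  pr <- make_random_problem("weibull", "clayton", n = 10, seed = 61)
  tg <- exp(seq(-4, 3, length.out = 100))
  G <- censoring_survival(pr$spec, pr$coeffs, tg, pr$data$X)
  expect_true(all(G >= 0 & G <= 1))
  expect_true(all(apply(G, 1, function(r) all(diff(r) <= 0))))
  expect_equal(censoring_survival(pr$spec, pr$coeffs, 1e-30, pr$data$X)[, 1],
               rep(1, 10), tolerance = 1e-8)
  P <- params_at(pr$spec, pr$coeffs, pr$data$X)
  expect_equal(G[, 7], 1 - margin_cdf(pr$spec$margin_C, tg[7], P[, 3], P[, 4]))
})
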