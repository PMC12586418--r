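test_that("link functions round-trip and match Table-style conventions", {
  expect_equal(copula_link_inv(copula_spec("gaussian"), 0), 0)
  expect_equal(copula_link_inv(copula_spec("gumbel"), 0), 2)
  expect_equal(copula_link_inv(copula_spec("clayton"), 3.5), exp(3.5))
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    eta <- seq(-3, 3, length.out = 25)
    expect_equal(copula_link(cs, copula_link_inv(cs, eta)), eta,
                 tolerance = 1e-9)
  }
})

test_that("Kendall's tau conversions hit the dependence-range anchors", {
  # Setting-1 style predictor extremes eta = 0.5 and 3.5
  expect_equal(round(kendall_tau(copula_spec("clayton"), exp(0.5)), 2), 0.45)
  expect_equal(round(kendall_tau(copula_spec("clayton"), exp(3.5)), 2), 0.94)
  expect_equal(round(kendall_tau(copula_spec("gaussian"), tanh(0.5)), 2), 0.31)
  expect_equal(round(kendall_tau(copula_spec("gaussian"), tanh(3.5)), 2), 0.96)
  expect_equal(kendall_tau(copula_spec("gaussian"), 0), 0)
  expect_equal(kendall_tau(copula_spec("clayton"), 2), 0.5)
  expect_equal(kendall_tau(copula_spec("gumbel"), 2), 0.5)
})

test_that("copula CDF satisfies boundary identities and closed forms", {
  set.seed(4)
  u <- runif(20); v <- runif(20)
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    th <- rand_theta(fam, 1)
    expect_equal(copula_cdf(cs, u, 1, th), u, tolerance = 1e-9)
    expect_equal(copula_cdf(cs, 1, v, th), v, tolerance = 1e-9)
    expect_equal(copula_cdf(cs, u, 0, th), rep(0, 20))
    expect_equal(copula_cdf(cs, 0, v, th), rep(0, 20))
  }
  expect_equal(copula_cdf(copula_spec("gaussian"), 0.5, 0.5, 0), 0.25,
               tolerance = 1e-9)
  expect_equal(copula_cdf(copula_spec("clayton"), 0.5, 0.5, 2), 7^(-0.5))
})

test_that("Frechet-Hoeffding bounds hold on a grid", {
  set.seed(14)
  g <- seq(0.02, 0.98, length.out = 50)
  uv <- expand.grid(u = g, v = g)
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    for (th in rand_theta(fam, 20)) {
      C <- copula_cdf(cs, uv$u, uv$v, th)
      expect_true(all(C >= pmax(uv$u + uv$v - 1, 0) - 1e-8))
      expect_true(all(C <= pmin(uv$u, uv$v) + 1e-8))
    }
  }
})

test_that("h-functions equal copula partial derivatives", {
  set.seed(5)
  eps <- 1e-6
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    n <- 40
    u <- runif(n, 0.05, 0.95); v <- runif(n, 0.05, 0.95)
    th <- rand_theta(fam, n)
    fd_u <- (copula_cdf(cs, u + eps, v, th) -
               copula_cdf(cs, u - eps, v, th)) / (2 * eps)
    expect_equal(h_function(cs, "v_given_u", u, v, th), fd_u,
                 tolerance = 1e-6)
    fd_v <- (copula_cdf(cs, u, v + eps, th) -
               copula_cdf(cs, u, v - eps, th)) / (2 * eps)
    expect_equal(h_function(cs, "u_given_v", u, v, th), fd_v,
                 tolerance = 1e-6)
    expect_equal(h_function(cs, "v_given_u", u, 1, th), rep(1, n))
    expect_true(all(diff(h_function(cs, "v_given_u", 0.4,
                                    seq(.01, .99, by = .01), th[1])) >= 0))
  }
  # independence and Clayton closed forms
  expect_equal(h_function(copula_spec("gaussian"), "v_given_u", 0.3, 0.7, 0),
               0.7, tolerance = 1e-9)
  expect_equal(h_function(copula_spec("clayton"), "v_given_u", 0.5, 0.5, 2),
               8 * 7^(-1.5))
})

test_that("copula density integrates pointwise as a mixed difference", {
  set.seed(6)
  eps <- 1e-4
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    n <- 30
    u <- runif(n, 0.1, 0.9); v <- runif(n, 0.1, 0.9)
    th <- rand_theta(fam, n)
    mfd <- (copula_cdf(cs, u + eps, v + eps, th) -
              copula_cdf(cs, u + eps, v - eps, th) -
              copula_cdf(cs, u - eps, v + eps, th) +
              copula_cdf(cs, u - eps, v - eps, th)) / (4 * eps^2)
    expect_rel_equal(copula_density(cs, u, v, th), mfd, 1e-3)
    # exchangeability
    expect_equal(copula_density(cs, u, v, th), copula_density(cs, v, u, th),
                 tolerance = 1e-10)
  }
  expect_equal(copula_density(copula_spec("gaussian"), runif(5), runif(5), 0),
               rep(1, 5), tolerance = 1e-12)
})

test_that("h-function derivatives match finite differences", {
  set.seed(8)
  eps <- 1e-6
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    n <- 40
    u <- runif(n, 0.05, 0.95); v <- runif(n, 0.05, 0.95)
    th <- rand_theta(fam, n)
    for (cond in c("v_given_u", "u_given_v")) {
      d <- h_derivs(cs, cond, u, v, th)
      fd <- list(
        du = (h_function(cs, cond, u + eps, v, th) -
                h_function(cs, cond, u - eps, v, th)) / (2 * eps),
        dv = (h_function(cs, cond, u, v + eps, th) -
                h_function(cs, cond, u, v - eps, th)) / (2 * eps),
        dtheta = (h_function(cs, cond, u, v, th + eps) -
                    h_function(cs, cond, u, v, th - eps)) / (2 * eps))
      expect_rel_equal(d$du, fd$du, 1e-5)
      expect_rel_equal(d$dv, fd$dv, 1e-5)
      expect_rel_equal(d$dtheta, fd$dtheta, 1e-4)
    }
  }
  # gaussian independence: dh/dv = 1
  expect_equal(h_derivs(copula_spec("gaussian"), "v_given_u", 0.4, 0.6, 0)$dv,
               1, tolerance = 1e-12)
  # Clayton dh/dtheta stays finite towards the independence boundary and
  # approaches the small-theta evaluation smoothly
  d_tiny <- h_derivs(copula_spec("clayton"), "v_given_u", 0.3, 0.6, 1e-8)
  d_small <- h_derivs(copula_spec("clayton"), "v_given_u", 0.3, 0.6, 1e-3)
  expect_true(is.finite(d_tiny$dtheta))
  # the two evaluation points differ by 1e-3 in theta, so allow genuine
  # curvature of dh/dtheta on top of the chord bias
  expect_equal(d_tiny$dtheta, d_small$dtheta, tolerance = 0.05)
})

test_that("conditional-inversion sampling has the right margins and tau", {
  n <- 1e5
  for (fam in ALL_COPULAS) {
    cs <- copula_spec(fam)
    th <- switch(fam, clayton = 2, gaussian = 0.6, gumbel = 2)
    uv <- sample_pair(cs, rep(th, n), seed = 99)
    expect_gt(suppressWarnings(ks.test(uv[, "u"], "punif"))$p.value, 0.001)
    expect_gt(suppressWarnings(ks.test(uv[, "v"], "punif"))$p.value, 0.001)
    tau_hat <- cor(uv[1:2e4, "u"], uv[1:2e4, "v"], method = "kendall")
    expect_equal(tau_hat, kendall_tau(cs, th), tolerance = 0.015)
    # inverse really inverts
    set.seed(17)
    w <- runif(200); u <- runif(200)
    expect_equal(h_function(cs, "v_given_u", u,
                            h_inverse(cs, w, u, th), th), w,
                 tolerance = 1e-7)
  }
  uv0 <- sample_pair(copula_spec("gaussian"), rep(0, 2e4), seed = 1)
  expect_lt(abs(cor(uv0[, 1], uv0[, 2], method = "kendall")), 0.015)
})

test_that("invalid dependence parameters are rejected", {
  expect_error(copula_cdf(copula_spec("clayton"), .5, .5, -1), "domain")
  expect_error(h_function(copula_spec("gumbel"), "v_given_u", .5, .5, 1),
               "domain")
  expect_error(sample_pair(copula_spec("gaussian"), c(0.5, 1.2)), "domain")
})
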