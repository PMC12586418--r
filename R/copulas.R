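#' One-parameter copula families
#'
#' Specification object for the three exchangeable one-parameter copulas used
#' to couple the survival and censoring margins: Clayton (lower tail
#' dependence, \eqn{\theta \in (0, \infty)}, log link), Gaussian (no tail
#' dependence, \eqn{\rho \in (-1, 1)}, inverse hyperbolic tangent link) and
#' Gumbel (upper tail dependence, \eqn{\theta \in (1, \infty)}, shifted-log
#' link \eqn{\eta = \log(\theta - 1)}).
#'
#' @param family one of `"clayton"`, `"gaussian"`, `"gumbel"`.
#' @return an object of class `copula_spec`.
#' @examples
#' cs <- copula_spec("clayton")
#' kendall_tau(cs, theta = 2)  # 0.5
#' @export
copula_spec <- function(family = c("clayton", "gaussian", "gumbel")) {
  family <- match.arg(family)
  dom <- switch(family,
    clayton  = c(0, Inf),
    gaussian = c(-1, 1),
    gumbel   = c(1, Inf))
  link <- switch(family,
    clayton  = "log",
    gaussian = "atanh",
    gumbel   = "log-shifted-1")
  structure(list(family = family, theta_domain = dom, link = link),
            class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("<copula_spec> %s (theta in (%g, %g), link: %s)\n",
              x$family, x$theta_domain[1], x$theta_domain[2], x$link))
  invisible(x)
}

.check_theta <- function(spec, theta) {
  d <- spec$theta_domain
  if (any(!is.finite(theta)) || any(theta <= d[1]) || any(theta >= d[2]))
    .stopf("copula parameter 'theta' outside the open %s domain (%g, %g)",
           spec$family, d[1], d[2])
  invisible(TRUE)
}

# guards: boosting paths can push predictors to extremes
.guard_theta <- function(spec, theta) {
  switch(spec$family,
    clayton  = pmax(theta, 1e-10),
    gaussian = pmin(pmax(theta, -(1 - 1e-7)), 1 - 1e-7),
    gumbel   = pmax(theta, 1 + 1e-10))
}

#' Copula link functions
#'
#' `copula_link` maps the dependence parameter to the predictor scale,
#' `copula_link_inv` maps back (Clayton: \eqn{\theta = e^\eta}; Gaussian:
#' \eqn{\rho = \tanh\eta}; Gumbel: \eqn{\theta = 1 + e^\eta}).
#'
#' @param spec a [copula_spec()].
#' @param theta dependence parameter on the natural scale.
#' @param eta predictor-scale value.
#' @export
copula_link <- function(spec, theta) {
  .check_theta(spec, theta)
  switch(spec$family,
    clayton  = log(theta),
    gaussian = atanh(theta),
    gumbel   = log(theta - 1))
}

#' @rdname copula_link
#' @export
copula_link_inv <- function(spec, eta) {
  switch(spec$family,
    clayton  = .guard_theta(spec, exp(eta)),
    gaussian = .guard_theta(spec, tanh(eta)),
    gumbel   = .guard_theta(spec, 1 + exp(eta)))
}

# derivative d theta / d eta of the inverse link
.dtheta_deta <- function(spec, theta) {
  switch(spec$family,
    clayton  = theta,
    gaussian = (1 - theta) * (1 + theta),
    gumbel   = theta - 1)
}

#' Kendall's tau implied by the dependence parameter
#'
#' Closed forms: Clayton \eqn{\tau = \theta/(\theta+2)}, Gaussian
#' \eqn{\tau = (2/\pi)\arcsin\rho}, Gumbel \eqn{\tau = 1 - 1/\theta}.
#'
#' @inheritParams copula_link
#' @export
kendall_tau <- function(spec, theta) {
  .check_theta(spec, theta)
  switch(spec$family,
    clayton  = theta / (theta + 2),
    gaussian = (2 / pi) * asin(theta),
    gumbel   = 1 - 1 / theta)
}

#' Copula distribution function
#'
#' @inheritParams copula_link
#' @param u,v probabilities in `[0, 1]`.
#' @return `C(u, v | theta)`, vectorized over its arguments.
#' @export
copula_cdf <- function(spec, u, v, theta) {
  .check_theta(spec, theta)
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  out <- numeric(n)
  lo <- u <= 0 | v <= 0
  hi_u <- !lo & u >= 1
  hi_v <- !lo & v >= 1 & !hi_u
  out[hi_u] <- v[hi_u]
  out[hi_v] <- u[hi_v]
  inner <- !(lo | hi_u | hi_v)
  if (any(inner)) {
    ui <- .clip01(u[inner]); vi <- .clip01(v[inner]); th <- theta[inner]
    out[inner] <- switch(spec$family,
      clayton  = {
        la <- .clayton_logA(ui, vi, th)
        exp(-la / th)
      },
      gumbel   = {
        ls <- .gumbel_logS(ui, vi, th)
        exp(-exp(ls / th))
      },
      gaussian = .gaussian_cdf(ui, vi, th))
  }
  pmin(pmax(out, 0), 1)
}

# log(u^-theta + v^-theta - 1), stable for large theta (always >= 0)
.clayton_logA <- function(u, v, theta) {
  x1 <- -theta * log(u); x2 <- -theta * log(v)
  m <- pmax(x1, x2)
  m + log(exp(x1 - m) + exp(x2 - m) - exp(-m))
}

# log((-log u)^theta + (-log v)^theta)
.gumbel_logS <- function(u, v, theta) {
  .logsumexp2(theta * log(-log(u)), theta * log(-log(v)))
}

# Gaussian copula CDF via 1-d adaptive quadrature (off the hot path)
.gaussian_cdf <- function(u, v, rho) {
  a <- stats::qnorm(u); b <- stats::qnorm(v)
  s <- sqrt((1 - rho) * (1 + rho))
  mapply(function(ai, bi, ri, si) {
    if (abs(ri) < 1e-12) return(stats::pnorm(ai) * stats::pnorm(bi))
    stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((bi - ri * x) / si),
                     -Inf, ai, rel.tol = 1e-10)$value
  }, a, b, rho, s)
}

#' Conditional h-functions
#'
#' The h-function is the partial derivative of the copula CDF with respect to
#' one argument and equals the conditional distribution function of the other
#' uniform.  `conditioned = "v_given_u"` returns
#' \eqn{h(v|u) = \partial C(u,v)/\partial u}; `"u_given_v"` returns
#' \eqn{h(u|v) = \partial C(u,v)/\partial v}.
#'
#' @inheritParams copula_cdf
#' @param conditioned which conditional to evaluate.
#' @export
h_function <- function(spec, conditioned = c("v_given_u", "u_given_v"),
                       u, v, theta) {
  conditioned <- match.arg(conditioned)
  .check_theta(spec, theta)
  if (conditioned == "u_given_v") {
    tmp <- u; u <- v; v <- tmp   # exchangeable families
  }
  n <- max(length(u), length(v), length(theta))
  u <- .clip01(rep_len(u, n)); v0 <- rep_len(v, n); theta <- rep_len(theta, n)
  v <- .clip01(v0)
  h <- .h_vgu(spec, u, v, theta)
  # exact boundaries in the non-conditioning argument
  h[v0 >= 1] <- 1
  h[v0 <= 0] <- 0
  pmin(pmax(h, 0), 1)
}

# core h(v | u) = dC/du for interior (u, v)
.h_vgu <- function(spec, u, v, theta) {
  switch(spec$family,
    gaussian = {
      a <- stats::qnorm(u); b <- stats::qnorm(v)
      s <- sqrt((1 - theta) * (1 + theta))
      stats::pnorm((b - theta * a) / s)
    },
    clayton = {
      la <- .clayton_logA(u, v, theta)
      exp((-theta - 1) * log(u) + (-1 / theta - 1) * la)
    },
    gumbel = {
      lx <- log(-log(u))
      ls <- .gumbel_logS(u, v, theta)
      exp(-exp(ls / theta) + (theta - 1) * lx + (1 / theta - 1) * ls - log(u))
    })
}

#' Copula density
#'
#' @inheritParams copula_cdf
#' @return the copula density `c(u, v | theta)`.
#' @export
copula_density <- function(spec, u, v, theta) {
  .check_theta(spec, theta)
  n <- max(length(u), length(v), length(theta))
  u <- .clip01(rep_len(u, n)); v <- .clip01(rep_len(v, n))
  theta <- rep_len(theta, n)
  .copula_density_core(spec, u, v, theta)
}

.copula_density_core <- function(spec, u, v, theta) {
  switch(spec$family,
    gaussian = {
      a <- stats::qnorm(u); b <- stats::qnorm(v)
      s2 <- (1 - theta) * (1 + theta)
      exp(-(theta^2 * (a^2 + b^2) - 2 * theta * a * b) / (2 * s2)) / sqrt(s2)
    },
    clayton = {
      la <- .clayton_logA(u, v, theta)
      (1 + theta) * exp((-theta - 1) * (log(u) + log(v)) +
                        (-1 / theta - 2) * la)
    },
    gumbel = {
      lx <- log(-log(u)); ly <- log(-log(v))
      ls <- .gumbel_logS(u, v, theta)
      lb <- ls / theta
      exp(-exp(lb) + (theta - 1) * (lx + ly) + (2 / theta - 2) * ls -
            log(u) - log(v) + log1p((theta - 1) * exp(-lb)))
    })
}

#' Partial derivatives of the h-function
#'
#' Returns \eqn{\partial h/\partial u}, \eqn{\partial h/\partial v} and
#' \eqn{\partial h/\partial \theta} for the requested conditional, with `u`
#' and `v` referring to the original copula arguments (so for
#' `"v_given_u"`, `du` differentiates the conditioning argument and `dv`
#' equals the copula density).  Analytic for the Gaussian and Clayton
#' families; the Gumbel \eqn{\partial h/\partial\theta} uses a central
#' difference along the link path.
#'
#' @inheritParams h_function
#' @return list with elements `du`, `dv`, `dtheta`.
#' @export
h_derivs <- function(spec, conditioned = c("v_given_u", "u_given_v"),
                     u, v, theta) {
  conditioned <- match.arg(conditioned)
  .check_theta(spec, theta)
  n <- max(length(u), length(v), length(theta))
  u <- .clip01(rep_len(u, n)); v <- .clip01(rep_len(v, n))
  theta <- rep_len(theta, n)
  if (conditioned == "u_given_v") {
    d <- .h_vgu_derivs(spec, v, u, theta)
    list(du = d$dv, dv = d$du, dtheta = d$dtheta)
  } else {
    .h_vgu_derivs(spec, u, v, theta)
  }
}

# derivatives of h(v | u) w.r.t. u (conditioning), v and theta
.h_vgu_derivs <- function(spec, u, v, theta) {
  dens <- .copula_density_core(spec, u, v, theta)
  switch(spec$family,
    gaussian = {
      a <- stats::qnorm(u); b <- stats::qnorm(v)
      s2 <- (1 - theta) * (1 + theta); s <- sqrt(s2)
      z <- (b - theta * a) / s
      phiz <- stats::dnorm(z)
      list(du = -phiz * theta / (s * stats::dnorm(a)),
           dv = dens,
           dtheta = phiz * (theta * b - a) / (s2 * s))
    },
    clayton = {
      la <- .clayton_logA(u, v, theta)
      lu <- log(u); lv <- log(v)
      du <- -(theta + 1) *
        exp((-theta - 2) * lu + (-1 / theta - 2) * la +
              .log_expm1(-theta * lv))
      dtheta <- .clayton_h_dtheta(u, v, theta, la, lu, lv)
      list(du = du, dv = dens, dtheta = dtheta)
    },
    gumbel = {
      lx <- log(-log(u))
      ls <- .gumbel_logS(u, v, theta)
      lb <- ls / theta
      h <- exp(-exp(lb) + (theta - 1) * lx + (1 / theta - 1) * ls - log(u))
      bracket <- exp((theta - 1) * lx) + (theta - 1) * exp((theta - 2) * lx) -
        (theta - 1) * exp((2 * theta - 2) * lx - ls)
      du <- h * h * exp(exp(lb)) -
        exp(-exp(lb) - 2 * log(u) + (1 / theta - 1) * ls) * bracket
      dtheta <- .h_dtheta_fd(spec, u, v, theta)
      list(du = du, dv = dens, dtheta = dtheta)
    })
}

# analytic Clayton dh/dtheta with a finite-difference fallback near the
# independence boundary where the closed form cancels catastrophically
.clayton_h_dtheta <- function(u, v, theta, la, lu, lv) {
  h <- exp((-theta - 1) * lu + (-1 / theta - 1) * la)
  x1 <- -theta * lu; x2 <- -theta * lv
  out <- h * (-lu + la / theta^2 +
                (1 / theta + 1) * (exp(x1 - la) * lu + exp(x2 - la) * lv))
  small <- theta < 1e-4
  if (any(small))
    out[small] <- .h_dtheta_fd(copula_spec("clayton"),
                               u[small], v[small], theta[small])
  out
}

# chord approximation of dh/dtheta with a step that stays inside the open
# parameter domain even right at its lower boundary
.h_dtheta_fd <- function(spec, u, v, theta) {
  lo <- spec$theta_domain[1]
  s <- 1e-5 * pmax(abs(theta - lo), 1)
  t_hi <- theta + s
  t_lo <- pmax(theta - s, lo + 0.5 * (theta - lo))
  if (spec$family == "gaussian") t_hi <- pmin(t_hi, 1 - 1e-7)
  (.h_vgu(spec, u, v, t_hi) - .h_vgu(spec, u, v, t_lo)) / (t_hi - t_lo)
}

#' Sample dependent uniform pairs by conditional inversion
#'
#' Draws \eqn{u \sim U(0,1)}, \eqn{w \sim U(0,1)} and sets
#' \eqn{v = h^{-1}(w \mid u; \theta)}, so both margins are exactly uniform and
#' the pair has the requested copula.  The Gaussian and Clayton inverses are
#' closed form; the Gumbel inverse is found by vectorized bisection to 1e-10.
#'
#' @param spec a [copula_spec()].
#' @param theta vector of dependence parameters, one per pair.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return a two-column matrix with columns `u` and `v`.
#' @export
sample_pair <- function(spec, theta, seed = NULL) {
  .check_theta(spec, theta)
  if (!is.null(seed)) set.seed(seed)
  n <- length(theta)
  u <- stats::runif(n)
  w <- stats::runif(n)
  v <- h_inverse(spec, w, u, theta)
  cbind(u = u, v = v)
}

#' Inverse h-function
#'
#' Solves \eqn{h(v \mid u; \theta) = w} for `v`.
#' @inheritParams sample_pair
#' @param w target conditional probabilities in (0, 1).
#' @param u conditioning uniforms in (0, 1).
#' @export
h_inverse <- function(spec, w, u, theta) {
  .check_theta(spec, theta)
  n <- max(length(w), length(u), length(theta))
  w <- .clip01(rep_len(w, n)); u <- .clip01(rep_len(u, n))
  theta <- rep_len(theta, n)
  switch(spec$family,
    gaussian = {
      s <- sqrt((1 - theta) * (1 + theta))
      stats::pnorm(theta * stats::qnorm(u) + s * stats::qnorm(w))
    },
    clayton = {
      # v = (1 + u^-theta (w^(-theta/(theta+1)) - 1))^(-1/theta), in log space
      a <- theta / (theta + 1)
      lt <- -theta * log(u) + .log_expm1(-a * log(w))
      big <- lt > 30
      l1p <- ifelse(big, lt, log1p(exp(lt)))
      .clip01(exp(-l1p / theta))
    },
    gumbel = {
      lo <- rep(1e-12, n); hi <- rep(1 - 1e-12, n)
      for (i in seq_len(60)) {
        mid <- (lo + hi) / 2
        too_low <- .h_vgu(spec, u, mid, theta) < w
        lo[too_low] <- mid[too_low]
        hi[!too_low] <- mid[!too_low]
      }
      (lo + hi) / 2
    })
}
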