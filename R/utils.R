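# Internal numerical guards shared across modules.

# probabilities entering copula calls are kept strictly inside (0, 1)
.clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# times / densities are kept strictly positive before logs
.clip_pos <- function(x, lo = 1e-300) pmax(x, lo)

# log(exp(a) + exp(b)) without overflow
.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# log(expm1(x)) for x > 0 without overflow
.log_expm1 <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log(expm1(x[small]))
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
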