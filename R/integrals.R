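# Trapezoid-rule quadrature helpers, in linear and in log space.
#
# All first-passage observables are ratios and nested integrals of exp(+U) and
# exp(-U). |U| can reach thousands of kBT at high voltage, so every integral of
# an exponential is accumulated in log space with a running log-sum-exp; this
# is exactly invariant to additive shifts of U and cannot overflow.

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# log(exp(a) + exp(b)), elementwise, tolerating -Inf.
log_add <- function(a, b) {
  m <- pmax(a, b)
  d <- pmin(a, b) - m
  out <- m + log1p(exp(d))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log(exp(a) - exp(b)) for a >= b, tolerating a == b (-> -Inf).
log_sub <- function(a, b) {
  d <- b - a
  out <- a + log(-expm1(d))
  out[d >= 0] <- -Inf
  out[is.infinite(a) & a < 0] <- -Inf
  out
}

# log of the cumulative trapezoid integral of exp(logf) along x.
# Returns a vector the same length as x; element i is log int_{x[1]}^{x[i]}.
log_cumtrapz <- function(x, logf) {
  n <- length(x)
  out <- numeric(n)
  out[1] <- -Inf
  if (n < 2L) return(out)
  # log of each panel's trapezoid area
  panel <- log_add(logf[-1], logf[-n]) + log(diff(x) / 2)
  acc <- -Inf
  for (i in seq_len(n - 1L)) {
    acc <- log_add(acc, panel[i])
    out[i + 1L] <- acc
  }
  out
}

# Shared-grid check used by every profile combinator.
same_grid <- function(x1, x2, tol = 1e-9) {
  length(x1) == length(x2) && all(abs(x1 - x2) <= tol * max(1, max(abs(x1))))
}
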