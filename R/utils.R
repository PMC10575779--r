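# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Truncated-normal sampler via rejection; bounds are respected exactly.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, sd > 0)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Mean and variance of g(A) for A ~ TruncNormal(mean, sd, [lo, hi]),
# computed by numerical quadrature (used to anchor generator calibration).
truncnorm_moments <- function(g, mean, sd, lower, upper) {
  f <- function(a) stats::dnorm(a, mean, sd)
  z <- stats::integrate(f, lower, upper)$value
  m1 <- stats::integrate(function(a) g(a) * f(a), lower, upper)$value / z
  m2 <- stats::integrate(function(a) g(a)^2 * f(a), lower, upper)$value / z
  list(mean = m1, var = m2 - m1^2)
}

# Deterministic, row-order-invariant seed derived from data content, so that
# subsample-based fits are reproducible without hidden global state.
data_seed <- function(...) {
  vals <- unlist(lapply(list(...), function(x) as.numeric(x[is.finite(x)])))
  s <- sum(abs(vals)) + 0.7 * sum(vals^2 %% 97)
  as.integer(round(s * 1e4) %% 2147483629)
}

# Standardized mean difference with pooled SD (balance diagnostics).
smd <- function(x_case, x_control) {
  s <- sqrt((stats::var(x_case) + stats::var(x_control)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x_case) - mean(x_control)) / s
}

is_case <- function(diagnosis) diagnosis == "schizophrenia"

BANKS <- c("NSW-BTRC", "VBBN", "NIMH-HBCC")
DIAGNOSES <- c("control", "schizophrenia")
ANALYTES <- c("iron", "copper", "zinc", "ferritin")
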