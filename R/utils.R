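#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used when matching
#' percentages printed in pathology reports; base [round()] rounds half to
#' even, which makes e.g. `round(79.5)` give 80 or 78 depending on parity.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Solve for beta shape parameters with a fixed concentration (a + b) such
# that the scaled distribution on [lo, hi] has the requested median.
beta_shapes_from_median <- function(lo, hi, median, concentration = 5) {
  stopifnot(hi > lo, median > lo, median < hi, concentration > 0.2)
  m01 <- (median - lo) / (hi - lo)
  # qbeta is inaccurate (and warns) for extreme shapes; the root is well
  # inside the bracket for any interior median
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, concentration - a)) - m01
  a <- stats::uniroot(f, c(0.02, concentration - 0.02), tol = 1e-10)$root
  c(shape1 = a, shape2 = concentration - a)
}

# Beta shapes on [lo, hi] matched to a mean and standard deviation by
# moment inversion.
beta_shapes_from_moments <- function(lo, hi, mean, sd) {
  stopifnot(hi > lo, mean > lo, mean < hi, sd > 0)
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (v >= m * (1 - m)) {
    stop("requested sd is infeasible for a beta distribution on this range")
  }
  conc <- m * (1 - m) / v - 1
  c(shape1 = m * conc, shape2 = (1 - m) * conc)
}

# Dirichlet draws via normalized gammas; rows sum to 1.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Largest-remainder apportionment of `n` items into integer counts with
# the given fractions (sum to 1). Deterministic; ties broken by order.
apportion_counts <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, n >= 0)
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
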