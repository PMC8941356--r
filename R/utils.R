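#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used for
#' every printed rate and confidence bound in the package's tables.  Base R's
#' [round()] rounds half to even, which does not reproduce printed clinical
#' tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(c(0.25, 0.35), 1)  # 0.3, 0.4 -- not banker's rounding
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # small epsilon guards against 0.049999999 representations of exact ties
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow/underflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministically derive a module-level seed from a top-level seed.
# Kept below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483647)
}

# Draw from N(mu, 1) truncated to (0, Inf) when y = 1 and to (-Inf, 0] when
# y = 0, via tail-probability inversion (accurate far into the tails).
rtruncnorm_probit <- function(mu, y) {
  u <- runif(length(mu))
  out <- numeric(length(mu))
  pos <- y == 1L
  # P(N(mu,1) > 0) = pnorm(mu); sample a tail prob t in (0, pnorm(mu))
  if (any(pos)) {
    p <- pmax(pnorm(mu[pos]), 1e-300)
    out[pos] <- mu[pos] - qnorm(u[pos] * p)
  }
  if (any(!pos)) {
    p <- pmax(pnorm(-mu[!pos]), 1e-300)
    out[!pos] <- mu[!pos] + qnorm(u[!pos] * p)
  }
  out
}

# Draw one sample from Dirichlet(alpha) via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # pathological underflow guard
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
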