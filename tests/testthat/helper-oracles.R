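# Independent oracles: brute-force enumeration over all topic assignments
# and closed-form small-case results.  Everything here is computed from
# first principles (Dirichlet-multinomial integrals, probit terms), not via
# the package's samplers, so it can serve as ground truth for them.

# All K^T assignment vectors for T flattened tokens (rows).
enum_assignments <- function(K, T) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T)))
}

# log p(z) + log p(w | z) (+ optional response term) for one flat
# assignment vector.  docs: list of token-id vectors; response term is
# either the probit likelihood p(y | zbar; eta, gamma) when `y` is given,
# or the Gaussian utility density when `y_star` is given.
oracle_log_joint <- function(zvec, docs, V, K, alpha, beta,
                             y = NULL, y_star = NULL,
                             eta = NULL, gamma = NULL, X = NULL) {
  doc_of <- rep(seq_along(docs), lengths(docs))
  words <- unlist(docs, use.names = FALSE)
  lp <- 0
  for (d in seq_along(docs)) {
    zd <- zvec[doc_of == d]
    ndk <- tabulate(zd, K)
    lp <- lp + lgamma(K * alpha) - lgamma(length(zd) + K * alpha) +
      sum(lgamma(ndk + alpha) - lgamma(alpha))
  }
  nkv <- matrix(0, K, V)
  for (t in seq_along(words)) nkv[zvec[t], words[t]] <- nkv[zvec[t], words[t]] + 1
  nk <- rowSums(nkv)
  lp <- lp + K * (lgamma(V * beta) - V * lgamma(beta)) +
    sum(lgamma(nkv + beta)) - sum(lgamma(nk + V * beta))
  if (!is.null(eta)) {
    for (d in seq_along(docs)) {
      zd <- zvec[doc_of == d]
      zbar <- tabulate(zd, K) / length(zd)
      m <- sum(eta * zbar) + if (!is.null(X)) sum(gamma * X[d, ]) else 0
      if (!is.null(y)) {
        lp <- lp + if (y[d] == 1) pnorm(m, log.p = TRUE) else
          pnorm(-m, log.p = TRUE)
      } else if (!is.null(y_star)) {
        lp <- lp + dnorm(y_star[d] - m, log = TRUE)
      }
    }
  }
  lp
}

# Exact posterior over all assignments (named by collapsed label strings).
oracle_z_posterior <- function(docs, V, K, alpha, beta, ...) {
  T <- sum(lengths(docs))
  zz <- enum_assignments(K, T)
  lj <- apply(zz, 1, function(zv)
    oracle_log_joint(zv, docs, V, K, alpha, beta, ...))
  p <- exp(lj - max(lj))
  p <- p / sum(p)
  names(p) <- apply(zz, 1, paste, collapse = "")
  p
}

# Exact log marginal likelihood of the features, log P(w | K).
oracle_log_evidence <- function(docs, V, K, alpha, beta) {
  T <- sum(lengths(docs))
  zz <- enum_assignments(K, T)
  lj <- apply(zz, 1, function(zv)
    oracle_log_joint(zv, docs, V, K, alpha, beta))
  m <- max(lj)
  m + log(sum(exp(lj - m)))
}

# Mean of N(mu, 1) truncated to (0, Inf).
oracle_truncated_mean_pos <- function(mu) mu + dnorm(mu) / pnorm(mu)

# Rank-based AUC (Mann-Whitney) for a score against binary labels.
oracle_auc <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small deterministic corpus used by several Gibbs tests.
tiny_corpus <- function() {
  slda_corpus(documents = list(c(1L, 2L, 1L), c(3L, 1L), 2L),
              y = c(1L, 0L, 1L),
              X = matrix(c(1, 0, 1), ncol = 1,
                         dimnames = list(NULL, "x1")),
              vocabulary = c("a", "b", "c"))
}
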