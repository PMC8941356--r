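# Supervised LDA fitted by collapsed Gibbs sampling.
#
# Patients are documents, present features are words.  The binary 1-year
# CLTI-free-survival response enters through a probit regression on the
# empirical per-document topic-assignment proportions zbar_d = n_dk / n_d
# plus demographic covariates; the probit is handled by truncated-normal
# latent-utility augmentation so every conditional is available in closed
# form.  Topic-word and document-topic distributions are collapsed out of
# the token-level updates (Griffiths-Steyvers) and re-estimated from the
# retained count matrices.

#' Hyperparameters for the sLDA sampler
#'
#' @param K number of topics/clusters (>= 2).
#' @param alpha symmetric document-topic Dirichlet concentration; default
#'   `50 / K` (the usual collapsed-Gibbs convention).
#' @param beta symmetric topic-word Dirichlet concentration; default 0.1.
#' @param coef_prior_var variance of the zero-mean normal prior on the
#'   regression coefficients (eta, gamma); `Inf` gives the flat-prior /
#'   least-squares limit.  Default 10.
#' @param n_sweeps total Gibbs sweeps (default 2000).
#' @param burn_in sweeps discarded before retention (default 1000; must be
#'   < `n_sweeps`).
#' @param thin retain every `thin`-th post-burn-in sweep (default 10).
#' @param seed integer RNG seed.
#' @return validated list of class `slda_hyperparams`.
#' @export
slda_hyperparams <- function(K, alpha = 50 / K, beta = 0.1,
                             coef_prior_var = 10, n_sweeps = 2000,
                             burn_in = 1000, thin = 10, seed = 1L) {
  if (!(is.numeric(K) && K >= 2)) stop("K must be an integer >= 2")
  stopifnot(alpha > 0, beta > 0, coef_prior_var > 0, thin >= 1)
  if (!(burn_in < n_sweeps)) stop("burn_in must be < n_sweeps")
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 coef_prior_var = coef_prior_var,
                 n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "slda_hyperparams")
}

# Internal: flatten a corpus to token arrays and fresh count matrices for a
# given assignment vector z (1-based topics).
.gibbs_counts <- function(corpus, z, K) {
  doc_len <- lengths(corpus$documents)
  doc_of <- rep(seq_along(corpus$documents), doc_len)
  word_of <- unlist(corpus$documents, use.names = FALSE)
  n <- length(corpus$documents)
  V <- length(corpus$vocabulary)
  n_dk <- matrix(0L, n, K)
  n_kv <- matrix(0L, K, V)
  for (t in seq_along(z)) {
    n_dk[doc_of[t], z[t]] <- n_dk[doc_of[t], z[t]] + 1L
    n_kv[z[t], word_of[t]] <- n_kv[z[t], word_of[t]] + 1L
  }
  list(doc_of = doc_of, word_of = word_of, doc_len = as.integer(doc_len),
       n_dk = n_dk, n_kv = n_kv, n_k = as.integer(rowSums(n_kv)))
}

#' Full conditional over topics for one token
#'
#' The collapsed-Gibbs full conditional for token `i` of document `d`,
#' combining the document-topic and topic-word Polya-urn terms with the
#' Gaussian response term on the latent utility (when `state$eta` is
#' non-null).  Exposed mainly for verification against brute-force
#' enumeration of the joint.
#'
#' @param state list with `z` (list of per-document assignment vectors),
#'   and optionally `y_star`, `eta`, `gamma` for the supervised term.
#' @param corpus an [slda_corpus()].
#' @param d document index; `i` token position within document `d`.
#' @param hp an [slda_hyperparams()].
#' @return length-K probability vector summing to 1.
#' @export
conditional_z_distribution <- function(state, corpus, d, i, hp) {
  K <- hp$K; V <- length(corpus$vocabulary)
  z_flat <- unlist(state$z, use.names = FALSE)
  cnt <- .gibbs_counts(corpus, z_flat, K)
  w <- corpus$documents[[d]][i]
  k_cur <- state$z[[d]][i]
  # remove token (d, i)
  cnt$n_dk[d, k_cur] <- cnt$n_dk[d, k_cur] - 1L
  cnt$n_kv[k_cur, w] <- cnt$n_kv[k_cur, w] - 1L
  cnt$n_k[k_cur] <- cnt$n_k[k_cur] - 1L
  if (any(cnt$n_dk < 0) || any(cnt$n_kv < 0))
    stop("counts inconsistent with z")
  nd <- length(corpus$documents[[d]])
  p <- (cnt$n_dk[d, ] + hp$alpha) *
    (cnt$n_kv[, w] + hp$beta) / (cnt$n_k + V * hp$beta)
  if (!is.null(state$eta)) {
    gx <- if (ncol(corpus$X) > 0) sum(state$gamma * corpus$X[d, ]) else 0
    base <- sum(state$eta * cnt$n_dk[d, ])
    m <- (base + state$eta) / nd + gx
    p <- p * exp(-0.5 * (state$y_star[d] - m)^2)
  }
  p <- pmax(p, 1e-300)
  p / sum(p)
}

#' Sample the latent probit utilities
#'
#' Draws `y*_d ~ N(eta' zbar_d + gamma' x_d, 1)` truncated to `(0, Inf)`
#' when `y_d = 1` and to `(-Inf, 0]` when `y_d = 0` (the probit
#' data-augmentation step).
#'
#' @param state list with `n_dk` (document-topic counts), `eta`, `gamma`.
#' @param corpus an [slda_corpus()].
#' @return numeric vector of latent utilities.
#' @export
sample_latent_utilities <- function(state, corpus) {
  nd <- lengths(corpus$documents)
  zbar <- state$n_dk / nd
  mu <- as.numeric(zbar %*% state$eta) +
    if (ncol(corpus$X) > 0) as.numeric(corpus$X %*% state$gamma) else 0
  rtruncnorm_probit(mu, corpus$y)
}

#' Sample the regression coefficients
#'
#' Joint conjugate draw of `(eta, gamma)` from the normal posterior of the
#' augmented linear model `y* = [zbar | X] b + e`, `e ~ N(0, 1)`, with
#' prior `b ~ N(0, coef_prior_var I)`.  With `coef_prior_var = Inf` the
#' posterior mean is the least-squares solution (singular designs are an
#' error in that limit).
#'
#' @param state list with `n_dk` and `y_star`.
#' @param corpus an [slda_corpus()].
#' @param hp an [slda_hyperparams()].
#' @return list with `eta` (length K) and `gamma` (length P).
#' @export
sample_coefficients <- function(state, corpus, hp) {
  K <- hp$K; P <- ncol(corpus$X)
  n <- length(corpus$documents)
  if (n == 0) {  # empty design: draw from the prior
    if (!is.finite(hp$coef_prior_var))
      stop("empty design with infinite prior variance")
    b <- rnorm(K + P, 0, sqrt(hp$coef_prior_var))
    return(list(eta = b[seq_len(K)], gamma = b[K + seq_len(P)]))
  }
  zbar <- state$n_dk / lengths(corpus$documents)
  A <- cbind(zbar, corpus$X)
  prec <- crossprod(A)
  if (is.finite(hp$coef_prior_var))
    prec <- prec + diag(1 / hp$coef_prior_var, K + P)
  R <- tryCatch(chol(prec), error = function(e)
    stop("singular coefficient design (use a finite coef_prior_var)"))
  mean_b <- backsolve(R, backsolve(R, crossprod(A, state$y_star),
                                   transpose = TRUE))
  b <- as.numeric(mean_b + backsolve(R, rnorm(K + P)))
  list(eta = b[seq_len(K)], gamma = b[K + seq_len(P)])
}

#' Fit the supervised LDA model by collapsed Gibbs sampling
#'
#' Runs `n_sweeps` sweeps of (i) token-level topic updates with the
#' response term, (ii) truncated-normal latent-utility draws, and (iii) a
#' joint conjugate coefficient draw; retains every `thin`-th post-burn-in
#' state.  Point estimates are posterior means over retained samples of the
#' smoothed count ratios `phi_kv = (n_kv + beta) / (n_k + V beta)` and
#' `theta_dk = (n_dk + alpha) / (n_d + K alpha)`.
#'
#' @param corpus an [slda_corpus()].
#' @param hp an [slda_hyperparams()].
#' @param supervised set `FALSE` for an unsupervised LDA fit (response term
#'   dropped, coefficients fixed at zero).
#' @param update_coefficients set `FALSE` to hold `(eta, gamma)` fixed at
#'   their initial values while still sampling `z` and `y*` (used for
#'   exact-posterior verification on tiny corpora).
#' @param eta_init,gamma_init initial coefficient values (default 0).
#' @param keep_z retain the full assignment vector of each retained sample
#'   (memory-heavy; intended for small corpora).
#' @return object of class `slda_fit`: `phi_hat` (K x V), `theta_hat`
#'   (n x K), `eta_hat`, `gamma_hat`, coefficient samples, per-sweep
#'   log-likelihood trace (`loglik_w` is the collapsed feature
#'   log-likelihood log p(w|z); `loglik_y` the Gaussian utility term),
#'   retained per-sample `loglik_w`, final state, and `hp`.
#' @export
slda_fit <- function(corpus, hp, supervised = TRUE,
                     update_coefficients = TRUE,
                     eta_init = NULL, gamma_init = NULL, keep_z = FALSE) {
  stopifnot(inherits(corpus, "slda_corpus"), inherits(hp, "slda_hyperparams"))
  set.seed(hp$seed)
  K <- hp$K; V <- length(corpus$vocabulary)
  n <- length(corpus$documents); P <- ncol(corpus$X)
  z <- sample.int(K, sum(lengths(corpus$documents)), replace = TRUE)
  cnt <- .gibbs_counts(corpus, z, K)
  z0 <- as.integer(z - 1L)  # 0-based for the C++ sweep
  doc_of0 <- as.integer(cnt$doc_of - 1L)
  word_of0 <- as.integer(cnt$word_of - 1L)
  eta <- as.numeric(eta_init %||% rep(0, K))
  gamma <- as.numeric(gamma_init %||% rep(0, P))
  stopifnot(length(eta) == K, length(gamma) == P)
  y_star <- ifelse(corpus$y == 1L, 0.5, -0.5)
  gx <- if (P > 0) as.numeric(corpus$X %*% gamma) else numeric(n)

  n_ret <- (hp$n_sweeps - hp$burn_in) %/% hp$thin
  phi_acc <- matrix(0, K, V); theta_acc <- matrix(0, n, K)
  eta_samp <- matrix(NA_real_, n_ret, K)
  gamma_samp <- matrix(NA_real_, n_ret, P)
  ret_loglik_w <- numeric(n_ret)
  z_samp <- if (keep_z) matrix(NA_integer_, n_ret, length(z)) else NULL
  loglik_w <- numeric(hp$n_sweeps); loglik_y <- numeric(hp$n_sweeps)
  r <- 0L

  for (s in seq_len(hp$n_sweeps)) {
    cpp_z_sweep(z0, doc_of0, word_of0, cnt$n_dk, cnt$n_kv, cnt$n_k,
                cnt$doc_len, hp$alpha, hp$beta, y_star, eta, gx, supervised)
    if (supervised) {
      st <- list(n_dk = cnt$n_dk, eta = eta, gamma = gamma, y_star = y_star)
      y_star <- sample_latent_utilities(st, corpus)
      if (update_coefficients) {
        st$y_star <- y_star
        cf <- sample_coefficients(st, corpus, hp)
        eta <- cf$eta; gamma <- cf$gamma
        gx <- if (P > 0) as.numeric(corpus$X %*% gamma) else numeric(n)
      }
    }
    loglik_w[s] <- log_likelihood_given_z(cnt$n_kv, cnt$n_k, hp$beta)
    loglik_y[s] <- if (supervised) {
      mu <- as.numeric((cnt$n_dk / cnt$doc_len) %*% eta) + gx
      sum(-0.5 * (y_star - mu)^2 - 0.5 * log(2 * pi))
    } else NA_real_
    if (s > hp$burn_in && (s - hp$burn_in) %% hp$thin == 0L) {
      r <- r + 1L
      phi_acc <- phi_acc + (cnt$n_kv + hp$beta) / (cnt$n_k + V * hp$beta)
      theta_acc <- theta_acc + (cnt$n_dk + hp$alpha) /
        (cnt$doc_len + K * hp$alpha)
      eta_samp[r, ] <- eta
      if (P > 0) gamma_samp[r, ] <- gamma
      ret_loglik_w[r] <- loglik_w[s]
      if (keep_z) z_samp[r, ] <- z0 + 1L
    }
  }
  dimnames(phi_acc) <- list(paste0("topic_", seq_len(K)), corpus$vocabulary)
  structure(list(
    phi_hat = phi_acc / r,
    theta_hat = theta_acc / r,
    eta_hat = colMeans(eta_samp),
    gamma_hat = if (P > 0) colMeans(gamma_samp) else numeric(0),
    eta_samples = eta_samp, gamma_samples = gamma_samp,
    retained = list(loglik_w = ret_loglik_w, z = z_samp, n = r),
    loglik_trace = data.frame(sweep = seq_len(hp$n_sweeps),
                              loglik_w = loglik_w, loglik_y = loglik_y),
    state = list(z = split(z0 + 1L, cnt$doc_of), n_dk = cnt$n_dk,
                 n_kv = cnt$n_kv, n_k = cnt$n_k, y_star = y_star,
                 eta = eta, gamma = gamma),
    hp = hp, supervised = supervised, vocabulary = corpus$vocabulary),
    class = "slda_fit")
}

#' @export
print.slda_fit <- function(x, ...) {
  cat("Supervised LDA fit: K =", x$hp$K, "topics,",
      nrow(x$theta_hat), "documents,", length(x$vocabulary), "tokens;",
      x$retained$n, "retained samples\n")
  cat("eta_hat:", paste(round(x$eta_hat, 3), collapse = " "), "\n")
  invisible(x)
}

#' Predict the outcome probability for a patient
#'
#' `Phi(eta_hat' theta_d + gamma_hat' x_d)`: the posterior-mean probit
#' probability of 1-year CLTI-free survival given cluster probabilities and
#' demographic covariates.
#'
#' @param model an [slda_fit()].
#' @param theta_d length-K cluster-probability vector (on the simplex).
#' @param x_d covariate vector (length P; may be empty).
#' @return probability in (0, 1).
#' @export
predict_outcome_probability <- function(model, theta_d, x_d = numeric(0)) {
  stopifnot(abs(sum(theta_d) - 1) < 1e-6)
  pnorm(sum(model$eta_hat * theta_d) +
          if (length(x_d)) sum(model$gamma_hat * x_d) else 0)
}

#' Infer cluster proportions for a held-out document
#'
#' Deterministic fold-in under the fitted topic-word distribution: iterates
#' soft token-topic responsibilities `q_tk` proportional to
#' `theta_k phi_hat[k, w_t]` and the smoothed update
#' `theta = (sum_t q_t + alpha) / (n_d + K alpha)` to a fixed point.  Used
#' to score new patients with [predict_outcome_probability()].
#'
#' @param model an [slda_fit()].
#' @param doc integer vector of token word-ids.
#' @param alpha document-topic concentration (defaults to the fit's).
#' @param n_iter fixed-point iterations (default 50).
#' @return length-K probability vector.
#' @export
infer_theta <- function(model, doc, alpha = model$hp$alpha, n_iter = 50) {
  K <- model$hp$K
  phi_w <- model$phi_hat[, doc, drop = FALSE]  # K x n_d
  theta <- rep(1 / K, K)
  for (it in seq_len(n_iter)) {
    q <- phi_w * theta
    q <- sweep(q, 2, colSums(q), "/")
    theta <- (rowSums(q) + alpha) / (length(doc) + K * alpha)
  }
  theta
}

#' Collapsed feature log-likelihood log p(w | z)
#'
#' The Dirichlet-multinomial integral over topic-word distributions given
#' the topic assignments:
#' `sum_k [lgamma(V b) - V lgamma(b) + sum_v lgamma(n_kv + b) - lgamma(n_k + V b)]`.
#' This is the per-sample quantity averaged by the harmonic-mean evidence
#' estimator.
#'
#' @param n_kv K x V topic-word count matrix; `n_k` its row sums; `beta`
#'   the symmetric topic-word concentration.
#' @return scalar log-likelihood.
#' @export
log_likelihood_given_z <- function(n_kv, n_k, beta) {
  V <- ncol(n_kv); K <- nrow(n_kv)
  K * (lgamma(V * beta) - V * lgamma(beta)) +
    sum(lgamma(n_kv + beta)) - sum(lgamma(n_k + V * beta))
}

#' Align fitted topics to reference topics
#'
#' Exhaustive search over topic permutations minimizing the mean absolute
#' difference between `phi` rows and `phi_ref` rows; used to undo label
#' switching before comparing a fit to simulation truth.
#'
#' @param phi fitted K x V topic-word matrix; `phi_ref` reference.
#' @return integer permutation `perm` such that `phi[perm, ]` best matches
#'   `phi_ref`.
#' @export
align_topics <- function(phi, phi_ref) {
  K <- nrow(phi)
  stopifnot(K == nrow(phi_ref), K <= 8)
  perms <- .permutations(K)
  costs <- apply(perms, 1, function(p) mean(abs(phi[p, ] - phi_ref)))
  perms[which.min(costs), ]
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}
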