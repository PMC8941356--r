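# Choosing the number of clusters by approximate marginal likelihood.
#
# For each candidate K the model is fitted and the marginal probability of
# the observed features P(w | K) is approximated by the harmonic mean of
# the per-sample collapsed likelihoods p(w | z) over retained posterior
# samples.  The harmonic-mean estimator is simple and matches the cited
# estimation strategy, but is known to be unstable (it can be dominated by
# rare low-likelihood samples); the retained-sample count is configurable
# and the full evidence table is always returned for inspection.

#' Harmonic-mean estimate of the log evidence
#'
#' `log P(w) ~= -log mean(exp(-L_s))` over per-sample log-likelihoods
#' `L_s = log p(w | z_s)`, computed with a log-sum-exp shift so values
#' spanning thousands of nats neither overflow nor underflow.
#'
#' @param per_sample_loglik numeric vector of retained log-likelihoods.
#' @return scalar log-evidence estimate.
#' @export
harmonic_mean_log_evidence <- function(per_sample_loglik) {
  if (length(per_sample_loglik) < 1) stop("need at least one retained sample")
  -(logsumexp(-per_sample_loglik) - log(length(per_sample_loglik)))
}

#' Evidence sweep over candidate numbers of clusters
#'
#' Fits the supervised model for each `K` in `K_range` (with a
#' deterministic per-K seed derived from `base_seed`) and estimates
#' `log P(w | K)` by [harmonic_mean_log_evidence()] over the retained
#' samples' collapsed feature log-likelihoods.  Returns the `K` with the
#' highest estimated evidence; exact ties break toward the smaller `K`.
#'
#' @param corpus an [slda_corpus()].
#' @param hp_template list of hyperparameter overrides applied at every K
#'   (e.g. `list(n_sweeps = 400, burn_in = 200, thin = 2)`).  Unless
#'   supplied, `alpha` defaults to a *constant* 3 for every candidate:
#'   comparing marginal likelihoods across K is only meaningful when the
#'   candidates share the same document-topic prior, whereas a `50 / K`
#'   schedule makes the prior sharper as K grows, which (with the short
#'   feature-documents and small vocabulary of this setting) mechanically
#'   inflates the harmonic-mean evidence of larger models.  A few prior
#'   pseudo-counts per topic -- comparable to the 5-12-token documents --
#'   keeps the posterior diffuse enough to feel the cost of superfluous
#'   topics; the selected K is flat over `alpha` in roughly 2..4.
#' @param K_range candidate cluster counts (default `2:9`).
#' @param base_seed seed from which each K's fitting seed is derived.
#' @param supervised passed through to [slda_fit()].
#' @return list of class `evidence_sweep`: `best_K`, `table` (data.frame
#'   `K`, `log_evidence`, `n_samples`), and `fits` (named list of
#'   `slda_fit` objects).
#' @export
select_k <- function(corpus, hp_template = list(), K_range = 2:9,
                     base_seed = 1L, supervised = TRUE) {
  K_range <- sort(unique(as.integer(K_range)))
  fits <- list(); rows <- list()
  for (K in K_range) {
    args <- hp_template
    args$K <- K
    if (is.null(args$alpha)) args$alpha <- 3
    args$seed <- derive_seed(base_seed, K)
    hp <- do.call(slda_hyperparams, args)
    fit <- tryCatch(slda_fit(corpus, hp, supervised = supervised),
                    error = function(e)
                      stop("fit failed at K = ", K, ": ", conditionMessage(e)))
    fits[[as.character(K)]] <- fit
    rows[[as.character(K)]] <- data.frame(
      K = K,
      log_evidence = harmonic_mean_log_evidence(fit$retained$loglik_w),
      n_samples = fit$retained$n)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  best_K <- table$K[which.max(table$log_evidence)]  # first max = smallest K
  structure(list(best_K = best_K, table = table, fits = fits),
            class = "evidence_sweep")
}

#' @export
print.evidence_sweep <- function(x, ...) {
  cat("Bayesian cluster-number selection (harmonic-mean evidence)\n")
  print(x$table, row.names = FALSE)
  cat("selected K =", x$best_K, "\n")
  invisible(x)
}

#' Elbow diagnostic on an evidence table
#'
#' Successive differences of the log-evidence across K: a "diminishing
#' returns" summary emitted for inspection alongside the argmax selection,
#' never used for automatic selection.
#'
#' @param table the `table` component of an `evidence_sweep`.
#' @return data.frame `K`, `delta_log_evidence` (NA for the first K).
#' @export
evidence_elbow <- function(table) {
  data.frame(K = table$K,
             delta_log_evidence = c(NA, diff(table$log_evidence)))
}
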