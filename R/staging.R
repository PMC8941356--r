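# Stage assignment and descriptive stage profiles.

#' Assign patients to stages by maximum cluster probability
#'
#' Each patient gets the stage whose posterior cluster probability is
#' highest.  Exact ties go to the smallest index and are reported in a
#' warning.
#'
#' @param theta_hat n x K matrix of cluster probabilities (rows on the
#'   simplex within `tol`).
#' @param tol row-sum tolerance (default 1e-6).
#' @return integer vector of 1-based stage labels.
#' @export
assign_stages <- function(theta_hat, tol = 1e-6) {
  theta_hat <- as.matrix(theta_hat)
  if (any(abs(rowSums(theta_hat) - 1) > tol))
    stop("theta rows must sum to 1 (simplex violation beyond tolerance)")
  labels <- max.col(theta_hat, ties.method = "first")
  mx <- theta_hat[cbind(seq_len(nrow(theta_hat)), labels)]
  ties <- rowSums(theta_hat == mx) > 1
  if (any(ties))
    warning(sum(ties), " patient(s) had tied cluster probabilities; ",
            "assigned to the smallest stage index")
  labels
}

#' Relabel stages by descending outcome rate
#'
#' Orders clusters so that stage 1 has the highest CLTI-free-survival rate
#' (best prognosis first, matching the usual clinical presentation).
#'
#' @param labels integer cluster labels.
#' @param clti_free logical outcome vector aligned with `labels`.
#' @return list: `labels` (relabeled), `order` (old label of each new
#'   stage).
#' @export
order_stages_by_outcome <- function(labels, clti_free) {
  rates <- vapply(sort(unique(labels)), function(s) {
    v <- clti_free[labels == s]
    mean(v %in% TRUE) / max(mean(!is.na(v)), 1e-12)
  }, numeric(1))
  old <- sort(unique(labels))[order(-rates)]
  new_labels <- match(labels, old)
  list(labels = new_labels, order = old)
}

#' Wald (normal-approximation) binomial confidence interval
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)` on the percent scale,
#' rounded half-up to one decimal and clamped to `[0, 100]`.  This interval
#' reproduces the published per-stage prevalence bounds exactly.
#'
#' @param count successes; `n` trials; `level` confidence level (0.95).
#' @return numeric `c(low, high)` in percent; `c(NA, NA)` when `n = 0`.
#' @export
#' @examples
#' wald_ci(28, 130)  # 14.5, 28.6
wald_ci <- function(count, n, level = 0.95) {
  stopifnot(count >= 0, count <= n)
  if (n == 0) return(c(low = NA_real_, high = NA_real_))
  p <- count / n
  half <- qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n) * 100
  lo <- max(0, round_half_up(100 * p - half, 1))
  hi <- min(100, round_half_up(100 * p + half, 1))
  c(low = lo, high = hi)
}

#' Difference of a stage prevalence from the cohort prevalence
#'
#' Signed difference in percentage points (stage minus cohort), rounded
#' half away from zero to one decimal.
#'
#' @param stage_prev,cohort_prev prevalences in percent (0..100).
#' @return signed percentage-point difference.
#' @export
difference_from_cohort <- function(stage_prev, cohort_prev) {
  stopifnot(stage_prev >= 0, stage_prev <= 100,
            cohort_prev >= 0, cohort_prev <= 100)
  round_half_up(stage_prev - cohort_prev, 1)
}

# Binary feature-presence matrix (n x V) from a corpus's documents.
.feature_presence <- function(corpus) {
  V <- length(corpus$vocabulary)
  m <- t(vapply(corpus$documents,
                function(d) as.numeric(tabulate(d, nbins = V) > 0),
                numeric(V)))
  colnames(m) <- corpus$vocabulary
  m
}

#' Build per-stage descriptive profiles
#'
#' For each stage: feature counts, prevalences with 95% Wald CIs,
#' percentage-point differences from the cohort prevalence, and outcome
#' numerators/denominators/rates (per-outcome denominators from the
#' missingness flags in `statuses`).  A cohort summary is included.
#'
#' @param features either an [slda_corpus()] (token presence defines the
#'   features) or a 0/1 matrix with named columns, one row per patient.
#' @param statuses outcome-status data.frame from [classify_cohort()].
#' @param labels integer stage label per patient.
#' @return list of class `stage_profiles`: `stages` (list of per-stage
#'   profile lists), `cohort` (same shape), `feature_table`,
#'   `outcome_table`, `delta_table`.
#' @export
build_stage_profiles <- function(features, statuses, labels) {
  if (inherits(features, "slda_corpus")) features <- .feature_presence(features)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(statuses),
            nrow(features) == length(labels))
  stage_ids <- sort(unique(labels))
  n_total <- nrow(features)
  cohort_counts <- colSums(features)
  cohort_prev <- 100 * cohort_counts / n_total

  profile_one <- function(idx, id) {
    n_s <- length(idx)
    counts <- colSums(features[idx, , drop = FALSE])
    prev <- if (n_s > 0) 100 * counts / n_s else rep(NA_real_, ncol(features))
    ci <- t(vapply(seq_along(counts), function(j) {
      if (n_s > 0) wald_ci(counts[j], n_s) else c(low = NA_real_, high = NA_real_)
    }, c(low = 0, high = 0)))
    ft <- data.frame(feature = colnames(features), count = as.integer(counts),
                     percent = round_half_up(prev, 1),
                     ci_low = ci[, "low"], ci_high = ci[, "high"],
                     stringsAsFactors = FALSE)
    delta <- if (n_s > 0)
      round_half_up(prev - cohort_prev, 1) else rep(NA_real_, length(prev))
    list(stage_id = id, n_patients = n_s, feature_prevalence = ft,
         delta_from_cohort = setNames(delta, colnames(features)),
         empty = n_s == 0)
  }

  stages <- lapply(stage_ids, function(s) profile_one(which(labels == s), s))
  cohort <- profile_one(seq_len(n_total), "cohort")
  outcome_table <- build_outcome_table(statuses, labels, stage_ids)

  feature_table <- do.call(rbind, lapply(stages, function(p) {
    cbind(stage = p$stage_id, p$feature_prevalence)
  }))
  feature_table <- rbind(feature_table,
                         cbind(stage = "cohort", cohort$feature_prevalence))
  delta_table <- do.call(rbind, lapply(stages, function(p) {
    data.frame(stage = p$stage_id, feature = names(p$delta_from_cohort),
               delta = unname(p$delta_from_cohort), stringsAsFactors = FALSE)
  }))
  structure(list(stages = stages, cohort = cohort,
                 feature_table = feature_table,
                 outcome_table = outcome_table,
                 delta_table = delta_table),
            class = "stage_profiles")
}

#' @export
print.stage_profiles <- function(x, ...) {
  cat("Stage profiles:", length(x$stages), "stages over",
      x$cohort$n_patients, "patients\n")
  print(x$outcome_table[x$outcome_table$outcome == "clti_free", ],
        row.names = FALSE)
  invisible(x)
}
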