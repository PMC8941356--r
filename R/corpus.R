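# Corpus container: patients as documents, present features as words.

#' Construct an sLDA corpus
#'
#' @param documents list of integer vectors; token word-ids (1-based into
#'   `vocabulary`).  Every document must be non-empty.
#' @param y binary response vector (1 = CLTI-free at 1 year).
#' @param X numeric covariate matrix (n x P, dummy-coded demographics; may
#'   have 0 columns).  Covariates enter only the outcome regression, never
#'   topic formation.
#' @param vocabulary ordered character vector of token names.
#' @return list of class `slda_corpus`.
#' @export
slda_corpus <- function(documents, y, X = matrix(0, length(documents), 0),
                        vocabulary) {
  n <- length(documents)
  if (!is.matrix(X)) X <- as.matrix(X)
  stopifnot(length(y) == n, nrow(X) == n)
  if (any(lengths(documents) == 0)) stop("every document must be non-empty")
  V <- length(vocabulary)
  ids <- unlist(documents, use.names = FALSE)
  if (length(ids) && (min(ids) < 1 || max(ids) > V))
    stop("token index outside vocabulary")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (anyNA(X)) stop("X must have no missing entries")
  structure(list(documents = lapply(documents, as.integer),
                 y = as.integer(y), X = X, vocabulary = vocabulary),
            class = "slda_corpus")
}

#' @export
print.slda_corpus <- function(x, ...) {
  cat("sLDA corpus:", length(x$documents), "documents,",
      length(x$vocabulary), "vocabulary tokens,",
      ncol(x$X), "covariates; mean document length",
      round(mean(lengths(x$documents)), 2), "\n")
  invisible(x)
}

# Canonical feature vocabulary of the staging model (order is stable so
# topic-word matrices are comparable across runs).
clti_vocabulary <- function() c(
  "wound_grade_1", "wound_grade_2", "wound_grade_3",
  "stroke", "renal_disease", "prior_cardiac_procedure",
  "myocardial_infarction", "hypercholesterolemia", "dialysis",
  "diabetes_type_1", "diabetes_type_2",
  "prior_procedure_index_leg", "prior_procedure_nonindex_leg",
  "smoker_never", "smoker_former", "smoker_current",
  "rest_pain",
  "bypass_tibial", "bypass_pedal",
  "bypass_popliteal_above_knee", "bypass_popliteal_below_knee")

#' Tokenize a cohort into an sLDA corpus
#'
#' One token per present binary feature and one per categorical feature
#' level (wound grade 1-3, diabetes type, smoking status, bypass target);
#' a grade-0 wound emits no token (absence is encoded by absence).  Sex and
#' race are dummy-coded into the covariate matrix only -- demographics are
#' deliberately kept out of topic formation and enter only the outcome
#' regression.
#'
#' @param patients data.frame of feature columns (as in
#'   [generate_cohort_records()]'s `$patients`) -- must be complete.
#' @param wound_grades data.frame `patient_id`, `wound_grade` from
#'   [grade_cohort_wounds()], aligned by `patient_id`.
#' @param y binary response aligned with `patients` (1 = CLTI-free).
#' @param empty_document `"error"` (default) to reject patients with no
#'   present feature, or `"sentinel"` to emit a `no_findings` token.
#' @return an [slda_corpus()].
#' @export
tokenize_cohort <- function(patients, wound_grades, y,
                            empty_document = c("error", "sentinel")) {
  empty_document <- match.arg(empty_document)
  vocab <- clti_vocabulary()
  if (empty_document == "sentinel") vocab <- c(vocab, "no_findings")
  g <- wound_grades$wound_grade[match(patients$patient_id, wound_grades$patient_id)]
  if (anyNA(g)) stop("wound grade missing/underivable for some patients")
  binary_feats <- c("stroke", "renal_disease", "prior_cardiac_procedure",
                    "myocardial_infarction", "hypercholesterolemia",
                    "dialysis", "prior_procedure_index_leg",
                    "prior_procedure_nonindex_leg", "rest_pain")
  docs <- lapply(seq_len(nrow(patients)), function(i) {
    toks <- character(0)
    if (g[i] > 0) toks <- c(toks, paste0("wound_grade_", g[i]))
    for (f in binary_feats) {
      v <- patients[[f]][i]
      if (is.na(v)) stop("missing feature '", f, "' for patient ",
                         patients$patient_id[i])
      if (v == 1) toks <- c(toks, f)
    }
    if (!patients$diabetes[i] %in% c("none", "type_1", "type_2"))
      stop("missing feature 'diabetes' for patient ", patients$patient_id[i])
    if (patients$diabetes[i] != "none")
      toks <- c(toks, paste0("diabetes_", patients$diabetes[i]))
    toks <- c(toks, paste0("smoker_", patients$smoking[i]),
              paste0("bypass_", patients$bypass_target[i]))
    if (!length(toks)) {
      if (empty_document == "error")
        stop("patient ", patients$patient_id[i], " has zero present features")
      toks <- "no_findings"
    }
    match(toks, vocab)
  })
  X <- cbind(sex_male = as.numeric(patients$sex == "male"),
             race_asian = as.numeric(patients$race == "asian"),
             race_black = as.numeric(patients$race == "black"),
             race_hispanic = as.numeric(patients$race == "hispanic"),
             race_other = as.numeric(patients$race == "other"))
  slda_corpus(docs, y = y, X = X, vocabulary = vocab)
}
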