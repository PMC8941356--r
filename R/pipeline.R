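# End-to-end orchestration: raw records in, staged cohort and report out.

#' Pipeline configuration
#'
#' @param input_dir directory with `cohort.csv`, `wounds.csv`, `events.csv`
#'   (as written by [write_cohort()]); mutually exclusive with
#'   `synthetic_config`.
#' @param synthetic_config a [cohort_config()] to simulate the input cohort
#'   instead of reading files.
#' @param hyperparams list of [slda_hyperparams()] overrides applied at
#'   every candidate K.
#' @param K_range candidate cluster counts for model selection; a single
#'   value skips selection.
#' @param out_dir output directory for all artifacts.
#' @param seed mandatory top-level seed; all module seeds derive from it.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic_config = NULL,
                            hyperparams = list(), K_range = 2:9,
                            out_dir, seed) {
  if (is.null(input_dir) == is.null(synthetic_config))
    stop("give exactly one of input_dir or synthetic_config")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(input_dir = input_dir, synthetic_config = synthetic_config,
                 hyperparams = hyperparams, K_range = as.integer(K_range),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate raw cohort inputs
#'
#' Per-patient completeness check: a patient is analyzable when all feature
#' fields are present, the wound grade is derivable (no unresolvable
#' free-text location), and the composite outcome is classifiable.
#' Incomplete patients are listed and excluded, never silently dropped.
#'
#' @param cohort a `cohort_data` object.
#' @return list of class `validation_report`: `n_input`, `n_excluded`,
#'   `n_analyzable`, `excluded_ids`, plus the derived `wound_grades` and
#'   `statuses` for the analyzable set.
#' @export
validate_inputs <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  patients <- cohort$patients
  grades <- grade_cohort_wounds(cohort$wounds, patients$patient_id)
  ev <- cohort$events[match(patients$patient_id, cohort$events$patient_id), ]
  recs <- cbind(ev, wound_grade = grades$wound_grade)
  statuses <- classify_cohort(recs)
  feat_cols <- setdiff(names(patients), "patient_id")
  feat_ok <- !Reduce(`|`, lapply(patients[feat_cols], is.na))
  ok <- feat_ok & !is.na(grades$wound_grade) & !is.na(statuses$clti_free)
  structure(list(n_input = nrow(patients),
                 n_excluded = sum(!ok),
                 n_analyzable = sum(ok),
                 excluded_ids = patients$patient_id[!ok],
                 keep = ok,
                 wound_grades = grades,
                 statuses = statuses),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation:", x$n_input, "patients in,", x$n_excluded,
      "excluded (incomplete),", x$n_analyzable, "analyzable\n")
  invisible(x)
}

#' Run the full staging pipeline
#'
#' Wound grading -> outcome construction -> tokenization -> cluster-number
#' selection -> supervised fit at the best K -> maximum-probability stage
#' assignment (stages ordered by descending CLTI-free survival) -> stage
#' profiles.  All artifacts plus a manifest (config echo, seed, row counts,
#' exclusions) are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the run directory and the in-memory
#'   results (`validation`, `corpus`, `selection`, `fit`, `labels`,
#'   `profiles`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, K_range = config$K_range,
                   hyperparams = config$hyperparams,
                   package_version = as.character(utils::packageVersion("cltistage")),
                   completed = character(0))
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  step <- function(name) {
    manifest$completed <<- c(manifest$completed, name)
    write_manifest()
  }

  cohort <- if (!is.null(config$input_dir)) read_cohort(config$input_dir)
            else generate_cohort_records(config$synthetic_config)
  manifest$n_input <- nrow(cohort$patients); step("load")

  val <- validate_inputs(cohort)
  manifest$n_excluded <- val$n_excluded
  manifest$n_analyzable <- val$n_analyzable
  manifest$excluded_ids <- val$excluded_ids
  step("validate")

  keep <- val$keep
  patients <- cohort$patients[keep, , drop = FALSE]
  grades <- val$wound_grades[keep, , drop = FALSE]
  statuses <- val$statuses[keep, , drop = FALSE]
  write.csv(grades, file.path(config$out_dir, "wound_grades.csv"),
            row.names = FALSE)
  write.csv(statuses, file.path(config$out_dir, "outcome_status.csv"),
            row.names = FALSE)
  step("outcomes")

  corpus <- tokenize_cohort(patients, grades,
                            y = as.integer(statuses$clti_free))
  manifest$n_documents <- length(corpus$documents)
  manifest$vocabulary_size <- length(corpus$vocabulary)
  step("tokenize")

  hp_template <- config$hyperparams
  sel_seed <- derive_seed(config$seed, 101L)
  if (length(config$K_range) > 1) {
    sel <- select_k(corpus, hp_template, K_range = config$K_range,
                    base_seed = sel_seed)
    write.csv(sel$table, file.path(config$out_dir, "evidence.csv"),
              row.names = FALSE)
    best_K <- sel$best_K
  } else {
    sel <- NULL
    best_K <- config$K_range
  }
  manifest$best_K <- best_K; step("select_k")

  args <- hp_template
  args$K <- best_K
  if (is.null(args$alpha)) args$alpha <- 50 / best_K
  args$seed <- derive_seed(config$seed, 202L)
  fit <- slda_fit(corpus, do.call(slda_hyperparams, args))
  write.csv(fit$phi_hat, file.path(config$out_dir, "phi.csv"))
  write.csv(fit$theta_hat, file.path(config$out_dir, "theta.csv"),
            row.names = FALSE)
  write.csv(fit$loglik_trace, file.path(config$out_dir, "loglik_trace.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(eta = fit$eta_hat, gamma = fit$gamma_hat),
                       file.path(config$out_dir, "coefficients.json"),
                       digits = NA)
  step("fit")

  raw_labels <- assign_stages(fit$theta_hat)
  ord <- order_stages_by_outcome(raw_labels, statuses$clti_free)
  labels <- ord$labels
  write.csv(data.frame(patient_id = patients$patient_id, stage = labels),
            file.path(config$out_dir, "stages.csv"), row.names = FALSE)
  manifest$stage_sizes <- as.integer(table(factor(labels, levels = sort(unique(labels)))))
  step("assign_stages")

  profiles <- build_stage_profiles(corpus, statuses, labels)
  write.csv(profiles$feature_table,
            file.path(config$out_dir, "stage_profiles.csv"), row.names = FALSE)
  write.csv(profiles$outcome_table,
            file.path(config$out_dir, "outcome_rates.csv"), row.names = FALSE)
  write.csv(profiles$delta_table,
            file.path(config$out_dir, "delta_from_cohort.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(outcome_rates = profiles$outcome_table),
    file.path(config$out_dir, "outcome_rates.json"), digits = NA)
  step("profiles")

  invisible(list(run_dir = config$out_dir, validation = val, corpus = corpus,
                 selection = sel, fit = fit, labels = labels,
                 profiles = profiles))
}
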