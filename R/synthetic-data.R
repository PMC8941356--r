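# Seeded synthetic-data generators.
#
# Two generators: (i) abstract corpora drawn exactly from the supervised-LDA
# generative model with known parameters, used for parameter-recovery and
# model-selection experiments; (ii) a PREVENT III-like cohort emulator that
# produces raw patient records (features at published prevalences, raw
# wound-location records, 1-year event histories) for end-to-end pipeline
# runs.  All draws go through R's RNG under a config seed, so identical
# configs give bit-identical output.

#' Block-structured, well-separated topic-word distributions
#'
#' Each of the `K` topics places `within` probability mass uniformly on its
#' own contiguous block of the vocabulary and spreads the rest uniformly
#' over the other words.  A deterministic stand-in for "well-separated"
#' topics in simulation experiments.
#'
#' @param K number of topics; `V` vocabulary size; `within` in (0,1).
#' @return K x V row-stochastic matrix.
#' @export
separated_topics <- function(K, V, within = 0.8) {
  stopifnot(K >= 1, V >= K, within > 0, within < 1)
  cut <- floor(seq(0, V, length.out = K + 1))
  phi <- matrix(0, K, V)
  for (k in seq_len(K)) {
    block <- (cut[k] + 1):cut[k + 1]
    phi[k, ] <- (1 - within) / (V - length(block))
    phi[k, block] <- within / length(block)
  }
  phi
}

#' Configuration of the sLDA generative model
#'
#' @param n_docs number of documents (patients).
#' @param K_true true number of topics.
#' @param vocabulary character vector of token names (size V).
#' @param alpha symmetric Dirichlet concentration over topics (> 0).  The
#'   default 0.5 concentrates each document on one dominant topic, the
#'   regime that emulates distinct patient phenotype clusters; large values
#'   (e.g. `50 / K_true`) make every document an even topic mixture with no
#'   document-level cluster structure.
#' @param beta symmetric Dirichlet concentration over the vocabulary (> 0);
#'   only used when `phi_true` is `NULL`, in which case topic rows are drawn
#'   from Dirichlet(beta).
#' @param phi_true K_true x V row-stochastic topic-word matrix.
#' @param eta_true length-K_true topic regression coefficients.
#' @param gamma_true length-P covariate coefficients.
#' @param covariate_probs Bernoulli probabilities of the P binary
#'   demographic covariates.
#' @param doc_length_range inclusive integer range of tokens per document
#'   (support must be >= 1).
#' @param seed integer seed.
#' @return validated config list of class `slda_generative_config`.
#' @export
slda_generative_config <- function(n_docs, K_true,
                                   vocabulary = paste0("w", seq_len(20)),
                                   alpha = 0.5, beta = 0.1,
                                   phi_true = separated_topics(K_true, length(vocabulary)),
                                   eta_true = rep(0, K_true),
                                   gamma_true = numeric(0),
                                   covariate_probs = numeric(0),
                                   doc_length_range = c(5L, 12L),
                                   seed = 1L) {
  if (!(is.numeric(n_docs) && n_docs >= 1)) stop("invalid field: n_docs")
  if (!(is.numeric(K_true) && K_true >= 1)) stop("invalid field: K_true")
  if (!(alpha > 0)) stop("invalid field: alpha (must be > 0)")
  if (!(beta > 0)) stop("invalid field: beta (must be > 0)")
  V <- length(vocabulary)
  if (!is.matrix(phi_true) || nrow(phi_true) != K_true || ncol(phi_true) != V)
    stop("invalid field: phi_true (must be K_true x V)")
  if (any(abs(rowSums(phi_true) - 1) > 1e-12))
    stop("invalid field: phi_true (rows must sum to 1)")
  if (length(eta_true) != K_true) stop("invalid field: eta_true")
  if (length(gamma_true) != length(covariate_probs))
    stop("invalid field: gamma_true (length must match covariate_probs)")
  if (doc_length_range[1] < 1) stop("invalid field: doc_length_range (support must be >= 1)")
  structure(list(n_docs = as.integer(n_docs), K_true = as.integer(K_true),
                 vocabulary = vocabulary, alpha = alpha, beta = beta,
                 phi_true = phi_true, eta_true = eta_true,
                 gamma_true = gamma_true, covariate_probs = covariate_probs,
                 doc_length_range = as.integer(doc_length_range),
                 seed = as.integer(seed)),
            class = "slda_generative_config")
}

#' Draw a corpus from the sLDA generative model
#'
#' For each document: topic proportions `theta_d ~ Dirichlet(alpha)`; each
#' token drawn topic-then-word from `phi_true`; binary response
#' `y_d ~ Bernoulli(Phi(eta_true' zbar_d + gamma_true' x_d))` where `zbar_d`
#' is the *empirical* topic-assignment frequency vector of the document.
#'
#' @param config an [slda_generative_config()].
#' @return list with `corpus` (an [slda_corpus()]) and `truth` (theta, z,
#'   phi, eta, gamma).
#' @export
generate_slda_corpus <- function(config) {
  stopifnot(inherits(config, "slda_generative_config"))
  set.seed(config$seed)
  K <- config$K_true; V <- length(config$vocabulary)
  P <- length(config$covariate_probs)
  docs <- vector("list", config$n_docs)
  z_true <- vector("list", config$n_docs)
  theta_true <- matrix(0, config$n_docs, K)
  X <- matrix(0, config$n_docs, P)
  if (P > 0) {
    for (p in seq_len(P)) X[, p] <- rbinom(config$n_docs, 1, config$covariate_probs[p])
    colnames(X) <- paste0("x", seq_len(P))
  }
  y <- integer(config$n_docs)
  lens <- config$doc_length_range
  for (d in seq_len(config$n_docs)) {
    theta_true[d, ] <- rdirichlet1(rep(config$alpha, K))
    nd <- 0L
    while (nd < 1L) nd <- sample(lens[1]:lens[2], 1L)  # support >= 1 by config
    z <- sample.int(K, nd, replace = TRUE, prob = theta_true[d, ])
    w <- vapply(z, function(k) sample.int(V, 1L, prob = config$phi_true[k, ]), 1L)
    zbar <- tabulate(z, nbins = K) / nd
    mu <- sum(config$eta_true * zbar) +
      if (P > 0) sum(config$gamma_true * X[d, ]) else 0
    y[d] <- rbinom(1, 1, pnorm(mu))
    docs[[d]] <- w; z_true[[d]] <- z
  }
  corpus <- slda_corpus(docs, y = y, X = X, vocabulary = config$vocabulary)
  list(corpus = corpus,
       truth = list(theta = theta_true, z = z_true, phi = config$phi_true,
                    eta = config$eta_true, gamma = config$gamma_true))
}

#' Canonical cluster-study generative configuration
#'
#' The simulation family used throughout the package's cluster-recovery and
#' model-selection experiments: 3 well-separated topics over a 20-token
#' vocabulary ([separated_topics()] with 80% within-block mass), documents
#' concentrated on a dominant topic (`alpha = 0.5`, emulating patients that
#' belong predominantly to one phenotype cluster), strongly separated
#' outcome supervision (`eta_true = c(2, 0, -2)`, i.e. one good-prognosis
#' and one poor-prognosis cluster), and one balanced binary demographic
#' covariate with coefficient 0.5.  Document lengths 5-12 mirror the
#' presence-token encoding of the cohort tokenizer.
#'
#' @param n_docs number of simulated patients (default 1200).
#' @param seed integer seed.
#' @param ... overrides passed on to [slda_generative_config()].
#' @return an [slda_generative_config()].
#' @export
cluster_study_config <- function(n_docs = 1200, seed = 1L, ...) {
  args <- list(n_docs = n_docs, K_true = 3, eta_true = c(2, 0, -2),
               gamma_true = 0.5, covariate_probs = 0.5, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(slda_generative_config, args)
}

# Default feature prevalences of the emulated bypass cohort (published
# cohort-characteristics table; renal disease, myocardial infarction and
# dialysis from the per-stage table's cohort totals).
.default_prevalences <- function() list(
  wound_grade = c(g0 = 0.077, g1 = 0.232, g2 = 0.438, g3 = 0.253),
  stroke = 0.198,
  renal_disease = 0.254,
  prior_cardiac_procedure = 0.344,
  myocardial_infarction = 0.295,
  hypercholesterolemia = 0.549,
  dialysis = 0.120,
  diabetes = c(none = 0.354, type_2 = 0.310, type_1 = 0.336),
  prior_procedure_index_leg = 0.265,
  prior_procedure_nonindex_leg = 0.255,
  smoking = c(never = 0.252, former = 0.489, current = 0.259),
  rest_pain = 0.521,
  bypass_target = c(tibial = 0.549, pedal = 0.121,
                    popliteal_above_knee = 0.104, popliteal_below_knee = 0.226),
  male = 0.646,
  race = c(asian = 0.008, black = 0.179, hispanic = 0.078,
           white = 0.722, other = 0.013)
)

#' Configuration of the synthetic cohort emulator
#'
#' @param n_patients cohort size (default 1238, the analyzable cohort size
#'   of the emulated trial).
#' @param feature_prevalences named list of marginal prevalences; defaults
#'   from the published cohort table.  Categorical entries are named
#'   probability vectors summing to 1.
#' @param event_model list of 1-year event probabilities and the wound
#'   healing probability: `p_death`, `p_amputation`, `p_recurrence`,
#'   `p_heal`.
#' @param missingness_rates per-field missingness probabilities:
#'   `vital_status`, `amputation_status`, `recurrence_status`,
#'   `healing_status` (all default 0).
#' @param n_incomplete number of leading patients whose feature data are
#'   blanked out, to emulate enrollment records excluded for incomplete
#'   data (default 0).
#' @param seed integer seed.
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1238,
                          feature_prevalences = .default_prevalences(),
                          event_model = list(p_death = 0.16, p_amputation = 0.12,
                                             p_recurrence = 0.15, p_heal = 0.72),
                          missingness_rates = list(vital_status = 0,
                                                   amputation_status = 0,
                                                   recurrence_status = 0,
                                                   healing_status = 0),
                          n_incomplete = 0, seed = 1L) {
  probs <- unlist(feature_prevalences, use.names = FALSE)
  if (any(probs < 0 | probs > 1)) stop("invalid field: feature_prevalences (probabilities must lie in [0,1])")
  mr <- unlist(missingness_rates, use.names = FALSE)
  if (any(mr < 0 | mr > 1)) stop("invalid field: missingness_rates")
  ev <- unlist(event_model, use.names = FALSE)
  if (any(ev < 0 | ev > 1)) stop("invalid field: event_model")
  if (n_incomplete > n_patients) stop("invalid field: n_incomplete")
  structure(list(n_patients = as.integer(n_patients),
                 feature_prevalences = feature_prevalences,
                 event_model = event_model,
                 missingness_rates = missingness_rates,
                 n_incomplete = as.integer(n_incomplete),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Raw wound records realizing a target WIfI wound grade.
.wounds_for_grade <- function(grade, use_other) {
  toe <- function(n) sample(paste0("toe_", 1:5), n)
  rec <- function(location, kind, free_text = NA_character_)
    data.frame(location = location, kind = kind, free_text = free_text,
               stringsAsFactors = FALSE)
  if (grade == 0)
    return(data.frame(location = character(), kind = character(),
                      free_text = character(), stringsAsFactors = FALSE))
  if (grade == 1) {
    if (use_other) return(rec("other", "ulcer", "hallux"))
    return(rec(toe(1), "ulcer"))
  }
  if (grade == 2) {
    pick <- sample(3, 1)
    if (pick == 1) return(rec(toe(2), c("ulcer", "ulcer")))
    if (pick == 2) return(rec(toe(1), "gangrene"))
    return(rec("forefoot", "ulcer"))
  }
  pick <- sample(3, 1)                      # grade 3, sometimes plus a toe wound
  main <- if (pick == 1) {
    if (use_other) rec("other", "ulcer", "heel") else rec("hindfoot", "ulcer")
  } else if (pick == 2) rec("leg", "ulcer") else {
    rec(sample(c("forefoot", "hindfoot", "leg"), 1), "gangrene")
  }
  if (runif(1) < 0.3) main <- rbind(main, rec(toe(1), "ulcer"))
  main
}

#' Generate a synthetic cohort of raw patient records
#'
#' Features are sampled independently at the configured marginal
#' prevalences; wounds are emitted as raw location-level records (including
#' a fraction of free-text `other` locations that the grading module must
#' recode); 1-year events get uniform day offsets in 0..365; missingness is
#' applied per the configured rates.
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort_data`: `patients` (features + covariates),
#'   `wounds` (raw wound records), `events` (day offsets and status flags).
#' @export
generate_cohort_records <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  fp <- config$feature_prevalences
  pid <- sprintf("S%04d", seq_len(n))
  cat1 <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  patients <- data.frame(
    patient_id = pid,
    sex = ifelse(rbinom(n, 1, fp$male) == 1, "male", "female"),
    race = cat1(fp$race),
    stroke = rbinom(n, 1, fp$stroke),
    renal_disease = rbinom(n, 1, fp$renal_disease),
    prior_cardiac_procedure = rbinom(n, 1, fp$prior_cardiac_procedure),
    myocardial_infarction = rbinom(n, 1, fp$myocardial_infarction),
    hypercholesterolemia = rbinom(n, 1, fp$hypercholesterolemia),
    dialysis = rbinom(n, 1, fp$dialysis),
    diabetes = cat1(fp$diabetes),
    prior_procedure_index_leg = rbinom(n, 1, fp$prior_procedure_index_leg),
    prior_procedure_nonindex_leg = rbinom(n, 1, fp$prior_procedure_nonindex_leg),
    smoking = cat1(fp$smoking),
    rest_pain = rbinom(n, 1, fp$rest_pain),
    bypass_target = cat1(fp$bypass_target),
    stringsAsFactors = FALSE)

  grades <- sample(0:3, n, replace = TRUE, prob = fp$wound_grade)
  use_other <- runif(n) < 0.05
  wounds <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- .wounds_for_grade(grades[i], use_other[i])
    if (nrow(w) == 0) return(NULL)
    cbind(patient_id = pid[i], w, stringsAsFactors = FALSE)
  }))
  if (is.null(wounds))
    wounds <- data.frame(patient_id = character(), location = character(),
                         kind = character(), free_text = character(),
                         stringsAsFactors = FALSE)

  em <- config$event_model
  day <- function(hit) ifelse(hit, sample.int(366, n, replace = TRUE) - 1L, NA_integer_)
  died <- rbinom(n, 1, em$p_death) == 1
  amp <- rbinom(n, 1, em$p_amputation) == 1
  rec <- rbinom(n, 1, em$p_recurrence) == 1
  heal <- grades > 0 & rbinom(n, 1, em$p_heal) == 1
  mr <- config$missingness_rates
  events <- data.frame(
    patient_id = pid,
    death_day = day(died),
    amputation_day = day(amp),
    recurrence_day = day(rec),
    healed_day = day(heal),
    healed_status_at_1yr = ifelse(grades == 0, "unknown",
                                  ifelse(heal, "healed", "unhealed")),
    vital_status_known = runif(n) >= mr$vital_status,
    amputation_status_known = runif(n) >= mr$amputation_status,
    recurrence_status_known = runif(n) >= mr$recurrence_status,
    stringsAsFactors = FALSE)
  miss_heal <- runif(n) < mr$healing_status
  events$healed_day[miss_heal] <- NA_integer_
  events$healed_status_at_1yr[miss_heal & grades > 0] <- "unknown"

  if (config$n_incomplete > 0) {
    hole <- seq_len(config$n_incomplete)
    patients$rest_pain[hole] <- NA_integer_
    patients$diabetes[hole] <- NA_character_
    events$vital_status_known[hole] <- FALSE
    events$amputation_status_known[hole] <- FALSE
    events$recurrence_status_known[hole] <- FALSE
    events$death_day[hole] <- NA_integer_
    events$amputation_day[hole] <- NA_integer_
    events$recurrence_day[hole] <- NA_integer_
    events$healed_day[hole] <- NA_integer_
    events$healed_status_at_1yr[hole] <- "unknown"
  }
  structure(list(patients = patients, wounds = wounds, events = events,
                 config = config),
            class = "cohort_data")
}

#' Write a generated corpus and its simulation truth
#'
#' Writes `corpus.csv` (one row per token: document, position, token name),
#' `covariates.csv` (response and covariate matrix) and `truth.json`
#' (theta, z, phi, eta, gamma) for a corpus drawn by
#' [generate_slda_corpus()].
#'
#' @param sim the list returned by [generate_slda_corpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_slda_corpus <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  docs <- sim$corpus$documents
  tok <- data.frame(document = rep(seq_along(docs), lengths(docs)),
                    position = unlist(lapply(lengths(docs), seq_len)),
                    token = sim$corpus$vocabulary[unlist(docs)])
  paths <- file.path(dir, c("corpus.csv", "covariates.csv", "truth.json"))
  write.csv(tok, paths[1], row.names = FALSE)
  write.csv(cbind(y = sim$corpus$y, sim$corpus$X), paths[2], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[3], digits = NA)
  invisible(paths)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort a `cohort_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`cohort.csv`, `wounds.csv`,
#'   `events.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cohort.csv", "wounds.csv", "events.csv"))
  write.csv(cohort$patients, paths[1], row.names = FALSE)
  write.csv(cohort$wounds, paths[2], row.names = FALSE)
  write.csv(cohort$events, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files written by [write_cohort()]
#' @param dir directory containing `cohort.csv`, `wounds.csv`, `events.csv`.
#' @return a `cohort_data` object.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  structure(list(patients = rd("cohort.csv"), wounds = rd("wounds.csv"),
                 events = rd("events.csv"), config = NULL),
            class = "cohort_data")
}
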