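# Composite 1-year CLTI-free-survival endpoint and its components.
#
# A patient is CLTI-free at 1 year if alive, free of major ipsilateral
# amputation, free of CLTI recurrence, and (when an index wound was present)
# the wound healed before or at 1 year.  Component statuses may be missing
# independently: e.g. vital status can be unknown while a recurrence before
# the horizon still classifies the composite as failed.

#' Classify one patient's 1-year outcomes
#'
#' @param record a list (or one-row data.frame) with fields: `wound_grade`
#'   (0-3, or `NA` if not derivable), `death_day`, `amputation_day`,
#'   `recurrence_day`, `healed_day` (integer day offsets in 0..365 or `NA`),
#'   `healed_status_at_1yr` (`"healed"`, `"unhealed"`, `"unknown"`), and the
#'   status-known flags `vital_status_known`, `amputation_status_known`,
#'   `recurrence_status_known`.
#' @param horizon_days endpoint horizon; events on day `horizon_days` count
#'   (the published wording is "before or at 1 year"), default 365.
#' @return list of class `outcome_status` with logical (or `NA`) `clti_free`,
#'   `died`, `amputated`, `recurred`, and character `wound_healed` in
#'   `c("healed","unhealed","not_applicable", NA)`.
#' @export
classify_patient <- function(record, horizon_days = 365) {
  day_in <- function(d) !is.na(d) && d <= horizon_days

  died <- if (isTRUE(record$vital_status_known)) day_in(record$death_day) else NA
  amputated <- if (isTRUE(record$amputation_status_known)) {
    day_in(record$amputation_day)
  } else NA
  recurred <- if (isTRUE(record$recurrence_status_known)) {
    day_in(record$recurrence_day)
  } else NA
  # An event recorded before the horizon overrides an "unknown" flag for the
  # composite-relevant direction (recurrence recorded before loss to
  # follow-up of vital status keeps the patient classifiable).
  if (is.na(recurred) && day_in(record$recurrence_day)) recurred <- TRUE

  wg <- record$wound_grade
  hs <- record$healed_status_at_1yr %||% "unknown"
  wound_healed <-
    if (!is.na(wg) && wg == 0) "not_applicable"
    else if (day_in(record$healed_day) || identical(hs, "healed")) "healed"
    else if (identical(hs, "unhealed")) "unhealed"
    else NA_character_

  fail <- isTRUE(died) || isTRUE(amputated) || isTRUE(recurred) ||
    identical(wound_healed, "unhealed")
  ok <- identical(died, FALSE) && identical(amputated, FALSE) &&
    identical(recurred, FALSE) &&
    (identical(wound_healed, "healed") || identical(wound_healed, "not_applicable"))
  clti_free <- if (fail) FALSE else if (ok) TRUE else NA

  structure(list(clti_free = clti_free, died = died, amputated = amputated,
                 recurred = recurred, wound_healed = wound_healed),
            class = "outcome_status")
}

#' Classify a cohort of patient records
#'
#' @param records data.frame, one row per patient, with the fields of
#'   [classify_patient()] plus `patient_id`.
#' @inheritParams classify_patient
#' @return data.frame of statuses, one row per patient.
#' @export
classify_cohort <- function(records, horizon_days = 365) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- classify_patient(as.list(records[i, , drop = FALSE]), horizon_days)
    data.frame(patient_id = records$patient_id[i],
               clti_free = s$clti_free, died = s$died,
               amputated = s$amputated, recurred = s$recurred,
               wound_healed = s$wound_healed, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentage with half-up rounding to one decimal
#'
#' @param numerator,denominator event and at-risk counts.
#' @return `100 * numerator / denominator` rounded half-up to one decimal;
#'   `NA` when the denominator is 0 (undefined rate).
#' @export
#' @examples
#' compute_rate(107, 130)  # 82.3
compute_rate <- function(numerator, denominator) {
  stopifnot(numerator >= 0, numerator <= denominator | denominator == 0)
  ifelse(denominator > 0, round_half_up(100 * numerator / denominator, 1),
         NA_real_)
}

#' Per-stage numerator/denominator table for all outcomes
#'
#' Each outcome uses its own denominator: the patients whose status for that
#' outcome is known (non-missing).  Denominators therefore differ between
#' outcomes within a stage; the printed "observed" convention for deaths,
#' amputations and recurrences is reproduced through the missingness flags
#' carried by the statuses.
#'
#' @param statuses data.frame from [classify_cohort()] (columns `clti_free`,
#'   `died`, `amputated`, `recurred`).
#' @param stage_labels integer stage label per patient, aligned with
#'   `statuses`.
#' @param stages stage ids to tabulate; defaults to the sorted labels
#'   present.  An id absent from `stage_labels` is an error.
#' @return data.frame with columns `stage` (including an `"overall"` row),
#'   `outcome`, `numerator`, `denominator`, `rate`.
#' @export
build_outcome_table <- function(statuses, stage_labels,
                                stages = sort(unique(stage_labels))) {
  stopifnot(nrow(statuses) == length(stage_labels))
  if (length(bad <- setdiff(stages, stage_labels)))
    stop("stage label(s) absent from data: ", paste(bad, collapse = ", "))
  outcomes <- c(clti_free = "clti_free", died = "died",
                amputated = "amputated", recurred = "recurred")
  one <- function(stage_name, idx) {
    do.call(rbind, lapply(names(outcomes), function(oc) {
      v <- statuses[[oc]][idx]
      num <- sum(v %in% TRUE)
      den <- sum(!is.na(v))
      data.frame(stage = stage_name, outcome = oc, numerator = num,
                 denominator = den,
                 rate = if (den > 0) compute_rate(num, den) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- do.call(rbind, lapply(stages, function(s) {
    one(as.character(s), which(stage_labels == s))
  }))
  rbind(tab, one("overall", seq_along(stage_labels)))
}
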