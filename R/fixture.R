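# Deterministic fixture reproducing the published stage and event counts of
# the PREVENT III nested-cohort staging analysis (1238 patients staged
# 130/578/530).  The cohort itself is not public; the fixture encodes the
# printed per-stage numerators and per-outcome denominators exactly, using
# missingness flags for the "observed"-denominator convention, so that the
# published rates are reproduced by construction and the rate/profile
# machinery can be validated against them.

#' Printed-count staging fixture
#'
#' Builds a synthetic 1238-patient cohort whose stage labels and
#' outcome-status table exactly reproduce the published per-stage counts:
#' stage sizes 130/578/530; CLTI-free 107/353/283; observed deaths 13/78/105
#' with mortality denominators 130/576/521; major amputations 5/55/81 with
#' denominators 119/509/440; recurrences 11/130/132 with denominators
#' 119/523/446.  Unknown statuses are encoded as `NA` so per-outcome
#' denominators fall out of [build_outcome_table()].  Patients with unknown
#' vital status have a recurrence recorded, which keeps them classifiable
#' for the composite.
#'
#' @return list with `stage` (integer labels, length 1238), `outcomes`
#'   (status data.frame as from [classify_cohort()]), and `stage_sizes`.
#' @export
#' @examples
#' fx <- prevent3_fixture()
#' table(fx$stage)
prevent3_fixture <- function() {
  n    <- c(130L, 578L, 530L)   # stage sizes
  surv <- c(107L, 353L, 283L)   # CLTI-free
  dth  <- c(13L, 78L, 105L); dth_den <- c(130L, 576L, 521L)
  amp  <- c(5L, 55L, 81L);   amp_den <- c(119L, 509L, 440L)
  rec  <- c(11L, 130L, 132L); rec_den <- c(119L, 523L, 446L)
  no_wound <- c(17L, 50L, 29L)  # patients without an index wound

  # Fill a status column over the non-survivor block: a block of NA first
  # (placed where recurrences are recorded, so unknown-vital-status patients
  # carry a recurrence), then the TRUE events, then known FALSE.
  col <- function(m, n_true, n_na) {
    c(rep(NA, n_na), rep(TRUE, n_true), rep(FALSE, m - n_na - n_true))
  }
  one_stage <- function(s) {
    m <- n[s] - surv[s]  # non-survivors
    died      <- col(m, dth[s], n[s] - dth_den[s])
    amputated <- c(rep(TRUE, amp[s]),
                   rep(FALSE, amp_den[s] - surv[s] - amp[s]),
                   rep(NA, m - (amp_den[s] - surv[s])))
    recurred  <- c(rep(TRUE, rec[s]),
                   rep(FALSE, rec_den[s] - surv[s] - rec[s]),
                   rep(NA, m - (rec_den[s] - surv[s])))
    data.frame(
      clti_free = c(rep(TRUE, surv[s]), rep(FALSE, m)),
      died      = c(rep(FALSE, surv[s]), died),
      amputated = c(rep(FALSE, surv[s]), amputated),
      recurred  = c(rep(FALSE, surv[s]), recurred),
      wound_healed = c(rep("not_applicable", no_wound[s]),
                       rep("healed", surv[s] - no_wound[s]),
                       rep("unhealed", m)),
      stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, lapply(1:3, one_stage))
  outcomes <- cbind(patient_id = sprintf("P%04d", seq_len(sum(n))), outcomes,
                    stringsAsFactors = FALSE)
  list(stage = rep(1:3, times = n), outcomes = outcomes, stage_sizes = n)
}

#' Printed per-stage feature counts
#'
#' The published per-stage feature-prevalence table as counts, for
#' regenerating its percentages and 95% CIs.  The printed "Diabetes" row
#' repeats the Dialysis counts and disagrees with its own percentages, so it
#' is omitted here; the type-1/type-2 diabetes rows are kept.
#'
#' @return data.frame `feature`, `stage1`, `stage2`, `stage3` counts, with
#'   stage sizes 130/578/530.
#' @export
prevent3_feature_counts <- function() {
  f <- function(feature, s1, s2, s3) data.frame(
    feature = feature, stage1 = s1, stage2 = s2, stage3 = s3,
    stringsAsFactors = FALSE)
  rbind(
    f("wound_grade_3", 28L, 157L, 135L),
    f("wound_grade_2", 49L, 253L, 240L),
    f("wound_grade_1", 36L, 125L, 126L),
    f("stroke", 22L, 115L, 108L),
    f("renal_disease", 24L, 149L, 142L),
    f("prior_cardiac_procedure", 34L, 210L, 182L),
    f("myocardial_infarction", 35L, 177L, 153L),
    f("hypercholesterolemia", 76L, 316L, 288L),
    f("dialysis", 9L, 66L, 74L),
    f("diabetes_type_2", 42L, 186L, 156L),
    f("diabetes_type_1", 40L, 186L, 190L),
    f("prior_procedure_index_leg", 31L, 157L, 140L),
    f("prior_procedure_nonindex_leg", 25L, 159L, 132L),
    f("smoker_never", 25L, 137L, 150L),
    f("smoker_former", 73L, 269L, 263L),
    f("smoker_current", 32L, 172L, 117L),
    f("rest_pain", 60L, 313L, 272L),
    f("bypass_tibial", 67L, 310L, 303L),
    f("bypass_pedal", 9L, 71L, 70L),
    f("bypass_popliteal_below_knee", 33L, 143L, 103L),
    f("bypass_popliteal_above_knee", 21L, 54L, 54L))
}
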