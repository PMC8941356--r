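# WIfI wound grade (0-3) from raw per-location wound records.
#
# Baseline wound examinations record ulcer and/or gangrene per location:
# each toe, the forefoot, the hindfoot, or a free-text "other" location.
# "Other" entries are recoded to an anatomical category by keyword lookup
# before grading; the grade for a limb is the highest grade among its
# wounds, with a single-toe ulcer (and nothing else) the only grade-1 case.

.wound_locations <- c(paste0("toe_", 1:5), "toes", "forefoot", "hindfoot",
                      "leg", "other")
.toe_locations <- c(paste0("toe_", 1:5), "toes")

#' Keyword table for recoding free-text wound locations
#'
#' Returns the shipped mapping from free-text keywords to anatomical wound
#' categories (`toes`, `forefoot`, `hindfoot`, `leg`).  The table lives in
#' `inst/extdata/wound_location_keywords.csv` and can be replaced or
#' extended by passing a custom table to [recode_other_location()].
#'
#' @return data.frame with columns `keyword` and `category`.
#' @export
wound_keyword_table <- function() {
  path <- system.file("extdata", "wound_location_keywords.csv",
                      package = "cltistage", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Recode a free-text "other" wound location
#'
#' Case-insensitive whole-word keyword lookup against a mapping table;
#' longer keywords are tried first so "great toe" wins over "toe".
#' Unresolvable strings return `NA` so the caller can flag the patient for
#' the missing-data path rather than silently dropping the wound.
#'
#' @param free_text character vector of free-text location descriptions.
#' @param table keyword table, by default [wound_keyword_table()].
#' @return character vector over `c("toes","forefoot","hindfoot","leg")`,
#'   with `NA` for unresolvable entries.
#' @export
#' @examples
#' recode_other_location(c("hallux", "heel", "dorsum of foot"))
recode_other_location <- function(free_text, table = wound_keyword_table()) {
  stopifnot(is.character(free_text))
  if (any(!nzchar(trimws(free_text)) | is.na(free_text)))
    stop("free_text must be non-empty for every 'other' wound record")
  kw <- table[order(-nchar(table$keyword)), , drop = FALSE]
  txt <- tolower(free_text)
  out <- rep(NA_character_, length(txt))
  for (i in seq_len(nrow(kw))) {
    pat <- paste0("\\b", gsub("([^[:alnum:] ])", "\\\\\\1", kw$keyword[i]), "\\b")
    hit <- is.na(out) & grepl(pat, txt)
    out[hit] <- kw$category[i]
  }
  out
}

#' Construct a wound-record table
#'
#' @param location character vector over the allowed locations: `toe_1` ...
#'   `toe_5`, `toes`, `forefoot`, `hindfoot`, `leg`, or `other`.
#' @param kind `"ulcer"` or `"gangrene"`, recycled.
#' @param free_text free-text description, required exactly when
#'   `location == "other"`.
#' @return data.frame of class `wound_records`.
#' @export
wound_records <- function(location = character(), kind = character(),
                          free_text = NA_character_) {
  n <- length(location)
  df <- data.frame(location = as.character(location),
                   kind = rep_len(as.character(kind), n),
                   free_text = rep_len(as.character(free_text), n),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$location, .wound_locations)
  if (length(bad)) stop("unknown wound location(s): ", paste(bad, collapse = ", "))
  if (!all(df$kind %in% c("ulcer", "gangrene")))
    stop("wound kind must be 'ulcer' or 'gangrene'")
  need_txt <- df$location == "other"
  if (any(need_txt & (is.na(df$free_text) | !nzchar(df$free_text))))
    stop("free_text is required for 'other' wound locations")
  if (any(!need_txt & !is.na(df$free_text) & nzchar(df$free_text)))
    stop("free_text is only allowed when location is 'other'")
  class(df) <- c("wound_records", "data.frame")
  df
}

# Grade of one wound record viewed in isolation.  A toe ulcer scores 1 here;
# grade_wound_set() upgrades multiple toe ulcers to 2.  Forefoot gangrene is
# graded 3 (highest-score resolution of the overlapping published rules);
# a forefoot ulcer, not covered by the published rules, is graded 2.
.record_grade <- function(location, kind) {
  is_toe <- location %in% .toe_locations
  ifelse(kind == "ulcer",
         ifelse(is_toe, 1L, ifelse(location == "forefoot", 2L, 3L)),
         ifelse(is_toe, 2L, 3L))
}

#' Grade one limb's wound set
#'
#' Applies the WIfI wound-grade rules to all wound records of one index leg:
#' grade 0 with no wound; grade 1 for an ulcer on only one toe; grade 2 for
#' ulcers on multiple toes or gangrene of toe(s); grade 3 for hindfoot/leg
#' ulcers or forefoot/hindfoot/leg gangrene; with multiple wounds the
#' highest grade wins.  `other` locations must be recoded first (see
#' [recode_other_location()]).
#'
#' @param records a `wound_records` table (or data.frame with the same
#'   columns) for a single patient's index leg.
#' @return object of class `wound_grade`: list with integer `value` in 0..3
#'   and the `contributing_records`.
#' @export
#' @examples
#' grade_wound_set(wound_records("toe_1", "ulcer"))$value          # 1
#' grade_wound_set(wound_records(c("toe_1","toe_3"), "ulcer"))$value # 2
grade_wound_set <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(structure(list(value = 0L,
                          contributing_records = wound_records()),
                     class = "wound_grade"))
  }
  if (any(records$location == "other")) {
    idx <- which(records$location == "other")[1]
    stop("wound record ", idx, " has un-recoded location 'other' (",
         records$free_text[idx], "); recode before grading")
  }
  bad <- setdiff(records$location, setdiff(.wound_locations, "other"))
  if (length(bad)) stop("unknown wound location(s): ", paste(bad, collapse = ", "))
  g <- max(.record_grade(records$location, records$kind))
  toe_ulcers <- unique(records$location[records$kind == "ulcer" &
                                          records$location %in% .toe_locations])
  if (length(toe_ulcers) >= 2) g <- max(g, 2L)
  structure(list(value = as.integer(g), contributing_records = records),
            class = "wound_grade")
}

#' Grade wounds for a whole cohort
#'
#' @param wounds data.frame with columns `patient_id`, `location`, `kind`,
#'   `free_text`; one row per wound record.
#' @param patient_ids ids to grade (patients absent from `wounds` get
#'   grade 0, i.e. no index wound).
#' @param keyword_table mapping used to recode `other` locations.
#' @return data.frame `patient_id`, `wound_grade` (integer, `NA` when a
#'   free-text location could not be resolved -- the missing-data path).
#' @export
grade_cohort_wounds <- function(wounds, patient_ids = unique(wounds$patient_id),
                                keyword_table = wound_keyword_table()) {
  grades <- setNames(rep(0L, length(patient_ids)), patient_ids)
  if (nrow(wounds)) {
    oth <- wounds$location == "other"
    if (any(oth)) {
      rec <- recode_other_location(wounds$free_text[oth], keyword_table)
      wounds$location[oth] <- rec
      wounds$free_text[oth] <- NA_character_
    }
    for (pid in intersect(unique(wounds$patient_id), patient_ids)) {
      rows <- wounds[wounds$patient_id == pid, , drop = FALSE]
      if (anyNA(rows$location)) {
        grades[[as.character(pid)]] <- NA_integer_  # unresolvable location
      } else {
        grades[[as.character(pid)]] <- grade_wound_set(rows)$value
      }
    }
  }
  data.frame(patient_id = patient_ids,
             wound_grade = unname(grades[as.character(patient_ids)]),
             stringsAsFactors = FALSE)
}

#' @export
print.wound_grade <- function(x, ...) {
  cat("WIfI wound grade:", x$value, "from", nrow(x$contributing_records),
      "wound record(s)\n")
  invisible(x)
}
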