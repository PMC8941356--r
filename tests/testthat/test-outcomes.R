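base_record <- function(...) {
  rec <- list(wound_grade = 2L, death_day = NA, amputation_day = NA,
              recurrence_day = NA, healed_day = NA,
              healed_status_at_1yr = "unknown",
              vital_status_known = TRUE, amputation_status_known = TRUE,
              recurrence_status_known = TRUE)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

test_that("composite classification follows the endpoint definition", {
  s <- classify_patient(base_record(healed_day = 200))
  expect_true(s$clti_free)
  expect_equal(s$wound_healed, "healed")

  s <- classify_patient(base_record(healed_status_at_1yr = "unhealed"))
  expect_false(s$clti_free)

  s <- classify_patient(base_record(death_day = 100))
  expect_false(s$clti_free)
  expect_true(s$died)

  # recurrence recorded before loss of vital status keeps the composite
  s <- classify_patient(base_record(vital_status_known = FALSE,
                                    recurrence_day = 180))
  expect_false(s$clti_free)
  expect_true(is.na(s$died))
  expect_true(s$recurred)

  # no index wound: healing not applicable
  s <- classify_patient(base_record(wound_grade = 0L))
  expect_true(s$clti_free)
  expect_equal(s$wound_healed, "not_applicable")

  # unknown healing with otherwise clean record: unclassifiable (exclusion)
  s <- classify_patient(base_record())
  expect_true(is.na(s$clti_free))

  # events after the horizon do not count
  s <- classify_patient(base_record(death_day = 300, healed_day = 10),
                        horizon_days = 200)
  expect_true(s$clti_free)
})

test_that("composite true implies every failure component false", {
  set.seed(21)
  for (i in 1:200) {
    rec <- base_record(
      wound_grade = sample(0:3, 1),
      death_day = if (runif(1) < .3) sample(0:365, 1) else NA,
      amputation_day = if (runif(1) < .3) sample(0:365, 1) else NA,
      recurrence_day = if (runif(1) < .3) sample(0:365, 1) else NA,
      healed_day = if (runif(1) < .5) sample(0:365, 1) else NA,
      healed_status_at_1yr = sample(c("healed", "unhealed", "unknown"), 1),
      vital_status_known = runif(1) < .9,
      amputation_status_known = runif(1) < .9,
      recurrence_status_known = runif(1) < .9)
    s <- classify_patient(rec)
    if (isTRUE(s$clti_free)) {
      expect_false(isTRUE(s$died) || isTRUE(s$amputated) || isTRUE(s$recurred))
      expect_true(s$wound_healed %in% c("healed", "not_applicable"))
    }
    # shrinking the horizon never flips an event-driven failure to success
    if (isFALSE(s$clti_free) && isTRUE(s$died)) {
      s2 <- classify_patient(rec, horizon_days = 400)
      expect_false(isTRUE(s2$clti_free) && rec$death_day <= 365)
    }
  }
})

test_that("rates round half-up to one decimal with an undefined sentinel", {
  expect_equal(compute_rate(107, 130), 82.3)
  expect_equal(compute_rate(743, 1238), 60.0)
  expect_equal(compute_rate(0, 50), 0.0)
  expect_equal(compute_rate(105, 521), 20.2)
  expect_true(is.na(compute_rate(0, 0)))
})

test_that("outcome table uses per-outcome denominators from missingness", {
  fx <- prevent3_fixture()
  tab <- build_outcome_table(fx$outcomes, fx$stage)
  cell <- tab[tab$stage == "3" & tab$outcome == "died", ]
  expect_equal(cell$numerator, 105)
  expect_equal(cell$denominator, 521)
  expect_equal(cell$rate, 20.2)

  # denominators never exceed stage size; numerators never exceed denominators
  sizes <- c("1" = 130, "2" = 578, "3" = 530, overall = 1238)
  expect_true(all(tab$denominator <= sizes[tab$stage]))
  expect_true(all(tab$numerator <= tab$denominator))

  # single stage, complete data: denominator equals n for every outcome
  st <- data.frame(clti_free = c(TRUE, FALSE, TRUE), died = c(FALSE, TRUE, FALSE),
                   amputated = FALSE, recurred = FALSE)
  tab1 <- build_outcome_table(st, rep(1, 3))
  expect_true(all(tab1$denominator == 3))

  # all-missing statuses: zero denominators, undefined rates
  stm <- data.frame(clti_free = NA, died = NA, amputated = NA, recurred = NA)
  tabm <- build_outcome_table(stm[rep(1, 4), ], rep(1, 4))
  expect_true(all(tabm$denominator == 0))
  expect_true(all(is.na(tabm$rate)))

  expect_error(build_outcome_table(st, rep(1, 3), stages = 2), "absent")
})
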