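test_that("stage assignment is the argmax with low-index tie-breaking", {
  theta <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.2, 0.7))
  expect_equal(assign_stages(theta), c(1L, 3L))
  expect_warning(lab <- assign_stages(rbind(rep(1 / 3, 3))), "tied")
  expect_equal(lab, 1L)
  expect_error(assign_stages(rbind(c(0.5, 0.2))), "simplex")

  set.seed(51)
  th <- matrix(rgamma(300 * 4, 1), 300, 4); th <- th / rowSums(th)
  expect_equal(assign_stages(th), apply(th, 1, which.max))
})

test_that("stages reorder by descending CLTI-free survival", {
  labels <- c(1, 1, 1, 2, 2, 2)
  y <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)  # cluster 2 does better
  out <- order_stages_by_outcome(labels, y)
  expect_equal(out$labels, c(2, 2, 2, 1, 1, 1))
  expect_equal(out$order, c(2, 1))
})

test_that("Wald intervals reproduce printed table cells", {
  expect_equal(wald_ci(28, 130), c(low = 14.5, high = 28.6))
  expect_equal(wald_ci(66, 578), c(low = 8.8, high = 14.0))
  expect_equal(wald_ci(49, 130), c(low = 29.4, high = 46.0))
  expect_equal(wald_ci(74, 530), c(low = 11.0, high = 16.9))
  expect_equal(wald_ci(172, 578), c(low = 26.0, high = 33.5))
  expect_equal(wald_ci(54, 530), c(low = 7.6, high = 12.8))
  expect_equal(wald_ci(0, 100), c(low = 0, high = 0))
  expect_true(all(is.na(wald_ci(0, 0))))
})

test_that("Wald coverage near p = 0.2, n = 130 sits in the documented band", {
  set.seed(52)
  hits <- replicate(2000, {
    x <- rbinom(1, 130, 0.2)
    ci <- wald_ci(x, 130)
    ci["low"] <= 20 && 20 <= ci["high"]
  })
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.97)
})

test_that("difference from cohort is signed, antisymmetric arithmetic", {
  expect_equal(difference_from_cohort(30, 30), 0)
  # stage-1 dialysis vs cohort dialysis from the printed per-stage counts
  cohort_dialysis <- 100 * (9 + 66 + 74) / 1238
  expect_equal(difference_from_cohort(100 * 9 / 130, cohort_dialysis), -5.1)
  expect_equal(difference_from_cohort(10, 25), -difference_from_cohort(25, 10))
})

test_that("stage profiles reproduce fixture rates and partition the cohort", {
  fx <- prevent3_fixture()
  feats <- matrix(rbinom(1238 * 2, 1, 0.3), 1238, 2,
                  dimnames = list(NULL, c("f1", "f2")))
  prof <- build_stage_profiles(feats, fx$outcomes, fx$stage)
  cf <- prof$outcome_table[prof$outcome_table$outcome == "clti_free", ]
  expect_equal(cf$rate[match(c("1", "2", "3"), cf$stage)], c(82.3, 61.1, 53.4))
  expect_equal(cf$rate[cf$stage == "overall"], 60.0)

  # partition: per-stage feature counts sum to cohort counts
  stage_counts <- sapply(prof$stages, function(p) p$feature_prevalence$count)
  expect_equal(rowSums(stage_counts), prof$cohort$feature_prevalence$count)
  expect_equal(sum(sapply(prof$stages, `[[`, "n_patients")), 1238)

  # one stage only: profile equals cohort, deltas vanish
  p1 <- build_stage_profiles(feats, fx$outcomes, rep(1, 1238))
  expect_equal(p1$stages[[1]]$feature_prevalence,
               p1$cohort$feature_prevalence)
  expect_true(all(p1$stages[[1]]$delta_from_cohort == 0))
})

test_that("printed per-stage prevalence cells regenerate from their counts", {
  counts <- prevent3_feature_counts()
  n <- c(stage1 = 130, stage2 = 578, stage3 = 530)
  # spot-check printed percent/CI cells across stages and features
  cases <- list(
    list("wound_grade_3", "stage1", 21.5, 14.5, 28.6),
    list("dialysis", "stage2", 11.4, 8.8, 14.0),
    list("wound_grade_2", "stage1", 37.7, 29.4, 46.0),
    list("smoker_current", "stage2", 29.8, 26.0, 33.5),
    list("dialysis", "stage3", 14.0, 11.0, 16.9),
    list("bypass_popliteal_above_knee", "stage3", 10.2, 7.6, 12.8),
    list("rest_pain", "stage1", 46.2, 37.6, 54.7),
    list("renal_disease", "stage2", 25.8, 22.2, 29.3))
  for (cs in cases) {
    cnt <- counts[counts$feature == cs[[1]], cs[[2]]]
    expect_equal(compute_rate(cnt, n[[cs[[2]]]]), cs[[3]])
    expect_equal(unname(wald_ci(cnt, n[[cs[[2]]]])), c(cs[[4]], cs[[5]]))
  }
})
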