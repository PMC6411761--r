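sheet_counts <- function(cohort) {
  sheets <- dplyr::distinct(cohort$responses, subject_id, timepoint)
  cg <- cohort$metadata$subject_id[cohort$metadata$group == "CG"]
  c(cg = sum(sheets$subject_id %in% cg),
    sg = sum(!sheets$subject_id %in% cg))
}

test_that("default design yields 40 control and 555 surgical sheets", {
  co <- simulate_cohort(seed = 1)
  expect_equal(nrow(co$metadata), 178)
  expect_equal(unname(sheet_counts(co)), c(40, 555))
  expect_equal(sum(co$metadata$t6_dropout), 77)

  # control subjects have exactly two sheets; dropout removes only T6
  sheets <- dplyr::count(co$responses, subject_id, timepoint)
  expect_true(all(sheets$n == 34))
  per_subj <- dplyr::count(dplyr::distinct(co$responses, subject_id, timepoint),
                           subject_id)
  cg <- co$metadata$subject_id[co$metadata$group == "CG"]
  expect_true(all(per_subj$n[per_subj$subject_id %in% cg] == 2))
  dropped <- co$metadata$subject_id[co$metadata$t6_dropout]
  t6 <- co$responses$subject_id[co$responses$timepoint == "T6"]
  expect_length(intersect(dropped, t6), 0)
  expect_equal(length(unique(t6)), 158 - 77)
})

test_that("the same seed reproduces the cohort bit for bit", {
  a <- simulate_cohort(seed = 99)
  b <- simulate_cohort(seed = 99)
  expect_identical(a$responses, b$responses)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$health, b$health)
  c2 <- simulate_cohort(seed = 100)
  expect_false(identical(a$responses, c2$responses))
})

test_that("noise-free configuration makes retest sheets identical to test", {
  cfg <- cohort_config(
    subject_factor_sd = 0, item_noise_sd = 0, retest_noise_sd = 0,
    control_health = c(0.8, 0)
  )
  co <- simulate_cohort(cfg, seed = 3)
  cg <- co$metadata$subject_id[co$metadata$group == "CG"]
  resp <- dplyr::filter(co$responses, subject_id %in% cg)
  wide <- tidyr::pivot_wider(resp, names_from = timepoint,
                             values_from = value)
  expect_equal(wide$test, wide$retest)
})

test_that("well-separated health distributions give disjoint total scores", {
  cfg <- cohort_config(
    control_health = c(0.95, 0.01),
    health_by_time = tibble::tibble(
      timepoint = c("T0", "T1", "T3", "T6"),
      mean = c(0.5, 0.78, 0.92, 0.96),
      sd = c(0.05, 0.08, 0.05, 0.04)
    ),
    subject_factor_sd = 0.1, item_noise_sd = 0.2, retest_noise_sd = 0.1
  )
  co <- simulate_cohort(cfg, seed = 5)
  cg <- co$metadata$subject_id[co$metadata$group == "CG"]
  totals <- score_responses(co$responses) |>
    dplyr::filter(scale == "total",
                  timepoint %in% c("test", "T0"))
  cg_tot <- totals$score[totals$subject_id %in% cg]
  sg_tot <- totals$score[!totals$subject_id %in% cg]
  expect_gt(min(cg_tot), max(sg_tot))
})

test_that("latent health drives scores monotonically", {
  co <- simulate_cohort(seed = 8)
  totals <- score_responses(co$responses) |>
    dplyr::filter(scale == "total") |>
    dplyr::inner_join(co$health, by = c("subject_id", "timepoint"))
  # strong but not perfect: the shared subject factor adds
  # health-independent rater variance by design
  expect_gt(stats::cor(totals$health, totals$score), 0.6)
})

test_that("trajectory summaries cover degenerate and default cohorts", {
  # constant perfect health, no noise -> all medians 100
  cfg <- cohort_config(
    health_by_time = tibble::tibble(
      timepoint = c("T0", "T1", "T3", "T6"),
      mean = 1, sd = 0
    ),
    control_health = c(1, 0),
    subject_factor_sd = 0, item_noise_sd = 0, retest_noise_sd = 0
  )
  tr <- trajectory_summary(simulate_cohort(cfg, seed = 2))
  expect_true(all(tr$median == 100))
  expect_true(all(tr$q3 - tr$q1 == 0))

  # single-subject summaries: median is that subject's score, IQR width 0
  one <- score_responses(make_sheet(1L))
  tr1 <- trajectory_summary(one)
  expect_true(all(tr1$median == 75))
  expect_true(all(tr1$q3 - tr1$q1 == 0))

  expect_error(trajectory_summary(one[0, ]), class = "bhsii_degenerate_error")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_t6_dropout = 158),
               class = "bhsii_config_error")
  expect_error(cohort_config(item_noise_sd = -1),
               class = "bhsii_config_error")
  expect_error(cohort_config(n_control = 0),
               class = "bhsii_config_error")
})
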