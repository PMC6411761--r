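scores_of <- function(sheet, ...) {
  sw <- scores_wide(score_responses(sheet, ...))
  as.list(sw[1, setdiff(names(sw), c("subject_id", "timepoint"))])
}

test_that("boundary sheets score at the ends of the 0-100 scale", {
  all0 <- scores_of(make_sheet(0L))
  expect_true(all(unlist(all0) == 100))

  all4 <- scores_of(make_sheet(4L))
  expect_true(all(unlist(all4) == 0))

  all1 <- score_responses(make_sheet(1L))
  expect_equal(all1$raw[all1$scale == "total"], 34)
  expect_equal(all1$score[all1$scale == "total"], 75)
})

test_that("domain normalization matches the published formula", {
  inst <- bhsii_instrument()
  p_items <- inst$item_id[inst$domain_code == "P"]
  sheet <- make_sheet(stats::setNames(rep(2L, 12), p_items))
  res <- score_domain(sheet, "P")
  expect_equal(res$raw, 24)
  expect_equal(res$score, 100 - 24 * 100 / 48) # = 50

  # full precision, not rounded: 100 - 1*100/48
  one <- make_sheet(stats::setNames(c(1L, rep(0L, 11)), p_items))
  expect_equal(score_domain(one, "P")$score, 100 - 100 / 48, tolerance = 1e-12)
})

test_that("raising any single item strictly lowers domain, section and total", {
  set.seed(42)
  inst <- bhsii_instrument()
  for (rep in 1:5) {
    sheet <- random_sheet()
    i <- sample(which(sheet$value < 4), 1)
    item <- sheet$item_id[i]
    dom <- inst$domain_code[inst$item_id == item]
    sec <- tolower(inst$section[inst$item_id == item])
    bumped <- sheet
    bumped$value[i] <- bumped$value[i] + 1L
    a <- scores_of(sheet)
    b <- scores_of(bumped)
    dom_scale <- c(P = "pain", S = "stiffness", F = "function",
                   V = "visual", M = "manual")[dom]
    expect_lt(b[[dom_scale]], a[[dom_scale]])
    expect_lt(b[[sec]], a[[sec]])
    expect_lt(b$total, a$total)
  }
})

test_that("scoring is permutation-invariant within a domain and raws are additive", {
  set.seed(7)
  inst <- bhsii_instrument()
  sheet <- random_sheet()
  p_rows <- which(sheet$item_id %in% inst$item_id[inst$domain_code == "P"])
  shuffled <- sheet
  shuffled$value[p_rows] <- sample(shuffled$value[p_rows])
  expect_equal(scores_of(sheet)$pain, scores_of(shuffled)$pain)

  long <- score_responses(sheet)
  dom_raw <- sum(long$raw[long$scale %in%
                            c("pain", "stiffness", "function",
                              "visual", "manual")])
  expect_equal(long$raw[long$scale == "total"], dom_raw)
})

test_that("every normalized score of random valid sheets lies in [0, 100]", {
  set.seed(11)
  for (rep in 1:20) {
    s <- score_responses(random_sheet())
    expect_true(all(s$score >= 0 & s$score <= 100))
  }
})

test_that("strict policy rejects incomplete sheets naming the missing item", {
  sheet <- make_sheet(1L)[-3, ] # drop P3
  expect_error(score_responses(sheet, missing = "strict"), "P3",
               class = "bhsii_missing_error")
})

test_that("prorate policy substitutes the domain mean when half answered", {
  inst <- bhsii_instrument()
  p_items <- inst$item_id[inst$domain_code == "P"]
  # 6 of 12 pain items answered with 2 -> prorated raw 24, score 50
  sheet <- make_sheet(1L)
  sheet <- sheet[!(sheet$item_id %in% p_items[7:12]), ]
  sheet$value[sheet$item_id %in% p_items[1:6]] <- 2L
  s <- score_responses(sheet, missing = "prorate")
  expect_equal(s$raw[s$scale == "pain"], 24)
  expect_equal(s$score[s$scale == "pain"], 50)
  # aggregates use the prorated domain raw
  expect_equal(s$raw[s$scale == "oq"], 24 + 5 + 7)

  # fewer than half answered: domain and containing aggregates undefined,
  # the untouched clinician section still scored
  sparse <- make_sheet(1L)
  sparse <- sparse[!(sparse$item_id %in% p_items[1:7]), ]
  s2 <- score_responses(sparse, missing = "prorate")
  expect_true(is.na(s2$score[s2$scale == "pain"]))
  expect_true(is.na(s2$score[s2$scale == "oq"]))
  expect_true(is.na(s2$score[s2$scale == "total"]))
  expect_equal(s2$score[s2$scale == "cr"], 75)
})
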