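test_that("AUC follows the pairwise count with ties at one half", {
  disjoint <- roc_analysis(c(50, 60), c(90, 95))
  expect_equal(disjoint$auc, 1)
  expect_equal(disjoint$sensitivity, 1)
  expect_equal(disjoint$specificity, 1)
  expect_true(disjoint$separable)
  expect_equal(disjoint$separating_lower, 50)
  expect_equal(disjoint$separating_upper, 60)

  overlap <- roc_analysis(c(1, 2, 3), c(2, 3, 4))
  expect_equal(overlap$auc, 7 / 9)
  expect_equal(overlap$threshold_criterion, "Youden")

  expect_warning(tie <- roc_analysis(5, 5), "constant")
  expect_equal(tie$auc, 0.5)
})

test_that("pairwise AUC equals the trapezoid under the empirical ROC", {
  set.seed(77)
  for (rep in 1:200) {
    nd <- sample(2:20, 1)
    nh <- sample(2:20, 1)
    d <- sample(0:30, nd, replace = TRUE)
    h <- sample(10:40, nh, replace = TRUE)
    if (stats::var(c(d, h)) == 0) next
    expect_equal(suppressWarnings(roc_analysis(d, h)$auc),
                 trapezoid_auc_oracle(d, h), tolerance = 1e-12)
  }
})

test_that("reversed orientation is flagged, empty groups rejected", {
  expect_warning(r <- roc_analysis(c(90, 95), c(50, 60)), "orientation")
  expect_lt(r$auc, 0.5)
  expect_error(roc_analysis(numeric(0), c(1, 2)),
               class = "bhsii_validation_error")
})

test_that("exact binomial bounds reproduce the closed forms", {
  expect_equal(round(clopper_pearson_ci(158, 158)$lower, 3), 0.977)
  expect_equal(round(clopper_pearson_ci(20, 20)$lower, 3), 0.832)
  expect_equal(clopper_pearson_ci(10, 10)$lower, 0.025^(1 / 10),
               tolerance = 1e-12)
  expect_equal(clopper_pearson_ci(0, 12)$lower, 0)
  expect_equal(clopper_pearson_ci(0, 12)$upper, 1 - 0.025^(1 / 12),
               tolerance = 1e-12)

  # binom.test's interval is the same exact construction
  for (x in c(0, 2, 7, 11, 15)) {
    ci <- clopper_pearson_ci(x, 15)
    bt <- stats::binom.test(x, 15)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-10)
  }
})

test_that("exact intervals bracket the estimate, tighten with n, and cover", {
  for (x in c(0, 3, 9, 15)) {
    ci <- clopper_pearson_ci(x, 15)
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
  }
  widths <- vapply(c(10, 20, 40, 80), function(n) {
    ci <- clopper_pearson_ci(round(0.8 * n), n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # exact coverage computed over the full binomial distribution
  p <- 0.3
  n <- 15
  covered <- vapply(0:n, function(x) {
    ci <- clopper_pearson_ci(x, n)
    ci$lower <= p && p <= ci$upper
  }, logical(1))
  expect_gte(sum(stats::dbinom(0:n, n, p) * covered), 0.95)
})

test_that("degenerate binomial counts are rejected", {
  expect_error(clopper_pearson_ci(5, 4), class = "bhsii_validation_error")
  expect_error(clopper_pearson_ci(-1, 4), class = "bhsii_validation_error")
  expect_error(clopper_pearson_ci(2.5, 4), class = "bhsii_validation_error")
})

test_that("correlation bands follow the BMJ cuts", {
  expect_equal(correlation_band(c(0.05, 0.3635, 0.45, 0.72, 0.9)),
               c("very weak", "weak", "moderate", "strong", "very strong"))
  expect_equal(correlation_band(-0.85), "very strong")
  expect_equal(correlation_band(1), "very strong")
})

test_that("spearman matrix matches the mid-rank oracle and is symmetric", {
  set.seed(15)
  tab <- tibble::tibble(
    a = c(3, 1, 4, 1, 5, 9, 2),
    b = c(2, 7, 1, 8, 2, 8, 1), # ties present
    c = stats::rnorm(7)
  )
  res <- spearman_matrix(tab)
  for (i in seq_len(nrow(res))) {
    row <- res[i, ]
    expect_equal(row$rho, spearman_oracle(tab[[row$scale_1]],
                                          tab[[row$scale_2]]),
                 tolerance = 1e-12)
  }
  ab <- res$rho[res$scale_1 == "a" & res$scale_2 == "b"]
  ba <- res$rho[res$scale_1 == "b" & res$scale_2 == "a"]
  expect_equal(ab, ba)
  expect_equal(res$rho[res$scale_1 == "a" & res$scale_2 == "a"], 1)
  expect_equal(res$band[res$scale_1 == "a" & res$scale_2 == "a"],
               "very strong")
})

test_that("spearman rho is invariant under monotone transforms", {
  set.seed(19)
  tab <- tibble::tibble(x = stats::rnorm(20), y = stats::rnorm(20))
  r1 <- spearman_matrix(tab)
  tab2 <- dplyr::mutate(tab, x = exp(x))
  r2 <- spearman_matrix(tab2)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
})

test_that("spearman p-values: t-approximation and exact permutation agree", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  res_t <- spearman_matrix(tibble::tibble(x, y))
  res_e <- spearman_matrix(tibble::tibble(x, y), p_method = "exact")
  expect_equal(res_t$rho, res_e$rho)
  # tie-free case: exact permutation p equals the classic exact Spearman p
  ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  pe <- res_e$p_value[res_e$scale_1 == "x" & res_e$scale_2 == "y"]
  expect_equal(pe, ct$p.value, tolerance = 1e-10)
})

test_that("constant columns yield NA cells, not a global failure", {
  tab <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  res <- spearman_matrix(tab)
  expect_true(is.na(res$rho[res$scale_1 == "a" & res$scale_2 == "b"]))
  expect_equal(res$rho[res$scale_1 == "a" & res$scale_2 == "a"], 1)
})
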