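#' ROC discrimination between diseased and healthy score distributions
#'
#' Empirical ROC analysis with the orientation fixed by the instrument's
#' semantics: lower scores mean more severe disease, so a sheet is
#' classified as diseased when its score falls at or below a threshold.
#' The AUC is the pairwise Mann--Whitney estimate: the proportion of
#' (diseased, healthy) pairs with the healthy score strictly higher, ties
#' counting one half.
#'
#' When the two groups are perfectly separable, the result carries the
#' observed diseased score interval `(separating_lower, separating_upper]`
#' (minimum and maximum diseased scores) and sensitivity/specificity at
#' the separating threshold, both 1 by construction, with Clopper--Pearson
#' 95% intervals reflecting the group sizes.  With overlap, the reported
#' threshold is the Youden-optimal one (maximizing sensitivity +
#' specificity).
#'
#' @param diseased_scores,healthy_scores Numeric score vectors for the two
#'   groups.
#' @param conf_level Confidence level for the exact binomial intervals.
#' @return An object of class `bhsii_roc`: `auc`, `accuracy_flag` (AUC >
#'   0.7, the conventional "moderate accuracy" cut), `threshold`,
#'   `sensitivity`/`specificity` with CI bounds, `separable`,
#'   `separating_lower`, `separating_upper`, and `curve` (a tibble of
#'   threshold, sensitivity, specificity, 1 - specificity).  `tidy()`
#'   returns the curve, `glance()` the summary row, `autoplot()` the ROC
#'   plot.
#' @examples
#' roc_analysis(c(50, 60), c(90, 95))$auc # disjoint groups -> 1
#' @export
roc_analysis <- function(diseased_scores, healthy_scores,
                         conf_level = 0.95) {
  d <- diseased_scores[!is.na(diseased_scores)]
  h <- healthy_scores[!is.na(healthy_scores)]
  if (length(d) == 0 || length(h) == 0) {
    stop_validation("both score groups must be non-empty")
  }
  if (stats::var(c(d, h)) == 0) {
    warning("pooled scores are constant: AUC = 0.5 by pure ties, ",
            "thresholds are meaningless")
  }

  # Pairwise Mann-Whitney estimate, ties count 1/2.
  cmp <- outer(h, d, ">") + 0.5 * outer(h, d, "==")
  auc <- mean(cmp)
  if (auc < 0.5) {
    warning("AUC below 0.5: check score orientation (low score = diseased)")
  }

  # Empirical curve over all observed thresholds (classify diseased if
  # score <= t).
  thresholds <- sort(unique(c(-Inf, d, h)))
  curve <- tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(d <= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(h > t), numeric(1))
  )
  curve$fpr <- 1 - curve$specificity

  separable <- max(d) < min(h)
  if (separable) {
    threshold <- max(d)
  } else {
    youden <- curve$sensitivity + curve$specificity
    threshold <- curve$threshold[which.max(youden)]
  }
  sens_x <- sum(d <= threshold)
  spec_x <- sum(h > threshold)
  sens_ci <- clopper_pearson_ci(sens_x, length(d), conf_level)
  spec_ci <- clopper_pearson_ci(spec_x, length(h), conf_level)

  structure(
    list(
      auc = auc,
      accuracy_flag = auc > 0.7,
      n_diseased = length(d), n_healthy = length(h),
      separable = separable,
      separating_lower = if (separable) min(d) else NA_real_,
      separating_upper = if (separable) max(d) else NA_real_,
      threshold = threshold,
      threshold_criterion = if (separable) "perfect separation" else "Youden",
      sensitivity = sens_x / length(d),
      sensitivity_ci = c(sens_ci$lower, sens_ci$upper),
      specificity = spec_x / length(h),
      specificity_ci = c(spec_ci$lower, spec_ci$upper),
      conf_level = conf_level,
      curve = curve
    ),
    class = "bhsii_roc"
  )
}

#' @export
print.bhsii_roc <- function(x, ...) {
  cat("<bhsii_roc> AUC = ", format(round(x$auc, 3)),
      "  (", x$n_diseased, " diseased vs ", x$n_healthy, " healthy)\n",
      sep = "")
  cat("  threshold ", format(x$threshold), " [", x$threshold_criterion,
      "]: sensitivity ", format(round(x$sensitivity, 3)),
      " (", format(round(100 * x$sensitivity_ci[1], 1)), "-",
      format(round(100 * x$sensitivity_ci[2], 1)), "%), specificity ",
      format(round(x$specificity, 3)),
      " (", format(round(100 * x$specificity_ci[1], 1)), "-",
      format(round(100 * x$specificity_ci[2], 1)), "%)\n", sep = "")
  if (x$separable) {
    cat("  diseased scores fall in (", format(x$separating_lower), ", ",
        format(x$separating_upper), "]\n", sep = "")
  }
  invisible(x)
}

#' Exact (Clopper--Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a proportion, via Beta quantiles:
#' `lower = qbeta(a/2, x, n - x + 1)`, `upper = qbeta(1 - a/2, x + 1,
#' n - x)`, with the closed-form boundary cases `x = 0` (lower 0, upper
#' `1 - (a/2)^(1/n)`) and `x = n` (lower `(a/2)^(1/n)`, upper 1).
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return A one-row tibble: `successes`, `n`, `estimate`, `lower`,
#'   `upper`, `conf_level`.
#' @examples
#' clopper_pearson_ci(158, 158)$lower # 0.977 to 3 dp
#' clopper_pearson_ci(20, 20)$lower   # 0.832 to 3 dp
#' @export
clopper_pearson_ci <- function(successes, n, conf_level = 0.95) {
  if (length(successes) != 1 || length(n) != 1 ||
      is.na(successes) || is.na(n) ||
      successes != round(successes) || n != round(n) ||
      n < 1 || successes < 0 || successes > n) {
    stop_validation("need integer counts with 0 <= successes <= n, n >= 1")
  }
  if (conf_level <= 0 || conf_level >= 1) {
    stop_validation("conf_level must be in (0, 1)")
  }
  a <- 1 - conf_level
  lower <- if (successes == 0) 0 else if (successes == n) {
    (a / 2)^(1 / n)
  } else {
    stats::qbeta(a / 2, successes, n - successes + 1)
  }
  upper <- if (successes == n) 1 else if (successes == 0) {
    1 - (a / 2)^(1 / n)
  } else {
    stats::qbeta(1 - a / 2, successes + 1, n - successes)
  }
  tibble::tibble(
    successes = as.integer(successes), n = as.integer(n),
    estimate = successes / n, lower = lower, upper = upper,
    conf_level = conf_level
  )
}

#' Qualitative band for a correlation coefficient
#'
#' Applies the conventional British Medical Journal bands to the absolute
#' value: 0--0.19 very weak, 0.2--0.39 weak, 0.40--0.59 moderate,
#' 0.6--0.79 strong, 0.8--1 very strong.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Character vector of band labels.
#' @examples
#' correlation_band(0.3635) # "weak"
#' @export
correlation_band <- function(r) {
  cut(abs(r),
      breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("very weak", "weak", "moderate", "strong", "very strong"),
      include.lowest = TRUE, right = FALSE,
      ordered_result = TRUE) |>
    as.character() |>
    (\(x) ifelse(abs(r) >= 1, "very strong", x))()
}

#' Spearman correlation matrix with qualitative banding
#'
#' Pairwise Spearman rank correlations between score columns, with
#' two-sided p-values and band labels.  The coefficient is the Pearson
#' correlation of mid-ranks (ties averaged); p-values use the
#' t-approximation `t = r sqrt((n-2)/(1-r^2))` by default, or the exact
#' permutation null for small samples.
#'
#' @param score_table Data frame or matrix of numeric columns (e.g. the
#'   wide per-subject score table from [scores_wide()]); non-numeric
#'   columns are dropped.
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   enumeration; only for 10 or fewer subjects).
#' @param sig_level Significance flag cutoff (default 0.05).
#' @return A tibble of class `bhsii_cor` with one row per ordered pair:
#'   `scale_1`, `scale_2`, `n`, `rho`, `p_value`, `band`, `significant`.
#'   Constant columns yield `NA` cells rather than an error for the whole
#'   matrix.  Reshape with [cor_matrix_wide()].
#' @export
spearman_matrix <- function(score_table, p_method = c("t", "exact"),
                            sig_level = 0.05) {
  p_method <- match.arg(p_method)
  df <- as.data.frame(score_table)
  df <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(df) < 2) stop_validation("need at least two numeric columns")
  if (nrow(df) < 4) stop_validation("need at least 4 subjects")
  cols <- names(df)
  pairs <- tidyr::expand_grid(scale_1 = cols, scale_2 = cols)
  res <- purrr::pmap_dfr(pairs, function(scale_1, scale_2) {
    ok <- stats::complete.cases(df[[scale_1]], df[[scale_2]])
    x <- df[[scale_1]][ok]
    y <- df[[scale_2]][ok]
    n <- length(x)
    if (n < 4 || stats::var(x) == 0 || stats::var(y) == 0) {
      return(tibble::tibble(
        scale_1 = scale_1, scale_2 = scale_2, n = n,
        rho = NA_real_, p_value = NA_real_
      ))
    }
    rho <- stats::cor(rank(x), rank(y))
    p <- spearman_p(rho, rank(x), rank(y), p_method)
    tibble::tibble(scale_1 = scale_1, scale_2 = scale_2, n = n,
                   rho = rho, p_value = p)
  })
  res$band <- correlation_band(res$rho)
  res$significant <- !is.na(res$p_value) & res$p_value < sig_level
  class(res) <- c("bhsii_cor", class(res))
  res
}

spearman_p <- function(rho, rx, ry, method) {
  n <- length(rx)
  if (method == "exact") {
    if (n > 10) stop_validation("exact permutation p only for n <= 10")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    return(mean(abs(null_rho) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Reshape a correlation result to matrix layout
#'
#' @param cor_result Output of [spearman_matrix()].
#' @param value Which cell value to spread: `"rho"` (default), `"p_value"`
#'   or `"band"`.
#' @return A tibble with one row per `scale_1` and one column per
#'   `scale_2`; the diagonal is `NA`.
#' @export
cor_matrix_wide <- function(cor_result, value = "rho") {
  stopifnot(value %in% c("rho", "p_value", "band"))
  out <- cor_result
  out[[value]][out$scale_1 == out$scale_2] <- NA
  tidyr::pivot_wider(
    dplyr::select(out, "scale_1", "scale_2", dplyr::all_of(value)),
    names_from = "scale_2", values_from = dplyr::all_of(value)
  )
}
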