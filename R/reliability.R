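#' Test-retest intraclass correlation
#'
#' ICC for two administrations of the same instrument to the same
#' subjects, computed from the two-way ANOVA mean squares.  The default
#' form is ICC(2,1) in the Shrout--Fleiss taxonomy -- two-way random
#' effects, absolute agreement, single measurement:
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with `MS_R` the between-subject, `MS_C` the between-administration and
#' `MS_E` the residual mean square.  A consistency form, ICC(3,1), which
#' ignores systematic administration shifts, is available via `type`.
#'
#' An ICC of at least 0.7 is conventionally read as adequate test-retest
#' stability; `glance()` reports this flag.
#'
#' @param test,retest Numeric vectors of scores, paired by subject.
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param threshold Stability flag cutoff (default 0.7).
#' @return An object of class `bhsii_icc` with the ICC value, model label,
#'   mean squares and dimensions.  Use [generics::tidy()] /
#'   [generics::glance()] for tibble output.
#' @examples
#' icc_test_retest(c(8, 7, 9, 6), c(8, 7, 9, 6))$icc # exact agreement -> 1
#' @export
icc_test_retest <- function(test, retest,
                            type = c("agreement", "consistency"),
                            threshold = 0.7) {
  type <- match.arg(type)
  if (length(test) != length(retest)) {
    stop_validation("test and retest must have the same length")
  }
  ok <- !is.na(test) & !is.na(retest)
  x <- cbind(test[ok], retest[ok])
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3) stop_degenerate("ICC needs at least 3 paired subjects")
  if (stats::var(as.vector(x)) == 0) {
    stop_degenerate("ICC undefined: all scores identical")
  }

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols

  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))

  icc <- if (type == "agreement") {
    (ms_rows - ms_error) /
      (ms_rows + (k - 1) * ms_error + (k / n) * (ms_cols - ms_error))
  } else {
    (ms_rows - ms_error) / (ms_rows + (k - 1) * ms_error)
  }
  label <- if (type == "agreement") {
    "ICC(2,1): two-way random effects, absolute agreement, single measure"
  } else {
    "ICC(3,1): two-way mixed effects, consistency, single measure"
  }
  structure(
    list(
      icc = icc, type = type, model_label = label,
      n_subjects = n, n_administrations = k,
      ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
      threshold = threshold, reliable = icc >= threshold
    ),
    class = "bhsii_icc"
  )
}

#' @export
print.bhsii_icc <- function(x, ...) {
  cat("<bhsii_icc> ", format(round(x$icc, 3)), "  [", x$model_label, "]\n",
      sep = "")
  cat("  n = ", x$n_subjects, " subjects x ", x$n_administrations,
      " administrations; stability flag (>= ", x$threshold, "): ",
      ifelse(x$reliable, "pass", "fail"), "\n", sep = "")
  invisible(x)
}

#' Cronbach's alpha internal consistency
#'
#' Computed from its defining variance decomposition,
#' \deqn{\alpha = k/(k-1) (1 - \sum_j \sigma^2_j / \sigma^2_T),}
#' where the item variances and the total-score variance are the usual
#' unbiased sample variances.  Alpha above 0.7 is conventionally read as
#' good internal consistency.
#'
#' @param item_matrix Numeric matrix or data frame, subjects in rows,
#'   items in columns.  Rows with any missing item are dropped.
#' @param threshold Consistency flag cutoff (default 0.7).
#' @return An object of class `bhsii_alpha`: `alpha`, `k` (items), `n`
#'   (subjects), `item_variances`, `total_variance`, flag.
#' @examples
#' m <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 3))
#' cronbach_alpha(m)$alpha # perfectly parallel items -> 1
#' @export
cronbach_alpha <- function(item_matrix, threshold = 0.7) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "numeric"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) stop_degenerate("Cronbach's alpha needs at least 2 items")
  if (n < 3) stop_degenerate("Cronbach's alpha needs at least 3 subjects")
  total <- rowSums(m)
  var_total <- stats::var(total)
  if (var_total == 0) {
    stop_degenerate("Cronbach's alpha undefined: constant total score")
  }
  item_vars <- apply(m, 2, stats::var)
  alpha <- k / (k - 1) * (1 - sum(item_vars) / var_total)
  structure(
    list(
      alpha = alpha, k = k, n = n,
      item_variances = item_vars, total_variance = var_total,
      threshold = threshold, consistent = alpha >= threshold
    ),
    class = "bhsii_alpha"
  )
}

#' @export
print.bhsii_alpha <- function(x, ...) {
  cat("<bhsii_alpha> ", format(round(x$alpha, 3)), "  (k = ", x$k,
      " items, n = ", x$n, ")\n", sep = "")
  cat("  consistency flag (>= ", x$threshold, "): ",
      ifelse(x$consistent, "pass", "fail"), "\n", sep = "")
  invisible(x)
}
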