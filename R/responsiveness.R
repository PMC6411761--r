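#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided paired Wilcoxon test.  Zero differences are discarded
#' (Wilcoxon's original rule); absolute differences are mid-ranked with
#' ties averaged and the statistic `V` is the rank sum of the positive
#' differences.  For 15 or fewer non-zero pairs the p-value is exact, by
#' enumeration of all `2^n` sign assignments of the observed (possibly
#' tied) ranks; beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param before,after Numeric vectors, paired by subject.
#' @param exact_limit Largest number of non-zero pairs for the exact path
#'   (default 15).
#' @return A one-row tibble: `statistic` (V, `NA` when every difference is
#'   zero), `p_value`, `n_used` (non-zero pairs), `method`.
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + 1) # exact two-sided p = 2/64
#' @export
wilcoxon_signed_rank <- function(before, after, exact_limit = 15L) {
  if (length(before) != length(after)) {
    stop_validation("before and after must have the same length")
  }
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = 1, n_used = 0L,
      method = "no non-zero differences"
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2

  if (n <= exact_limit) {
    # Distribution of the positive-rank sum over all 2^n equiprobable sign
    # assignments of the observed ranks.
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w <- as.vector(signs %*% r)
    p <- mean(abs(w - mu) >= abs(v - mu) - 1e-9)
    method <- "exact (sign-assignment enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal approximation (tie + continuity corrected)"
  }
  tibble::tibble(
    statistic = v, p_value = min(p, 1), n_used = n, method = method
  )
}

#' Kruskal--Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' `g - 1` degrees of freedom (delegating to [stats::kruskal.test()]).
#' When every observation is identical the statistic is 0 with p = 1
#' rather than undefined.
#'
#' @param values Numeric vector of scores, or a list of per-group numeric
#'   vectors (in which case `groups` is ignored).
#' @param groups Grouping vector aligned with `values`.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`,
#'   and `group_n` (list column of per-group counts).
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9)) # H = 7.2
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.factor(as.character(groups[ok]))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop_validation("need at least 2 non-empty groups")
  counts <- table(groups)
  if (any(counts == 0)) stop_validation("every group must be non-empty")
  if (stats::var(values) == 0) {
    res <- tibble::tibble(
      statistic = 0, df = nlevels(groups) - 1L, p_value = 1,
      n_groups = nlevels(groups)
    )
  } else {
    kt <- stats::kruskal.test(values, groups)
    res <- tibble::tibble(
      statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_value = kt$p.value, n_groups = nlevels(groups)
    )
  }
  res$group_n <- list(stats::setNames(as.integer(counts), names(counts)))
  res
}

#' Pearson chi-squared test of independence for a contingency table
#'
#' No continuity correction, matching the usual r x k analysis of
#' demographic tables (e.g. sex or affected limb by group).
#'
#' @param table Matrix of non-negative integer counts with at least 2 rows
#'   and 2 columns and strictly positive marginals.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(rbind(c(10, 0), c(0, 10))) # X2 = 20, df = 1
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop_validation("counts must be non-negative integers")
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop_validation("need at least a 2 x 2 table")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_validation("zero row or column marginal: test undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Longitudinal change tests over follow-up timepoints
#'
#' For each scale, runs the paired Wilcoxon test on every ordered pair of
#' timepoints, using only subjects scored at both (complete-case pairing),
#' alongside per-timepoint medians and IQRs.
#'
#' @param scores Long score table from [score_responses()] (surgical-group
#'   sheets).
#' @param timepoints Timepoints to compare, in temporal order.
#' @param scales Scales to test (default: all).
#' @return A list with `pairwise` (scale, timepoint pair, n pairs, V,
#'   p-value) and `summary` (the [trajectory_summary()] table).
#' @export
longitudinal_tests <- function(scores,
                               timepoints = c("T0", "T1", "T3", "T6"),
                               scales = bhsii_scales()) {
  wide <- scores |>
    dplyr::filter(.data$scale %in% scales,
                  .data$timepoint %in% timepoints) |>
    dplyr::select("subject_id", "timepoint", "scale", "score")
  tp_present <- intersect(timepoints, unique(wide$timepoint))
  pairs <- utils::combn(tp_present, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(
    intersect(bhsii_scales(), scales),
    function(sc) {
      sub <- tidyr::pivot_wider(
        dplyr::filter(wide, .data$scale == sc),
        names_from = "timepoint", values_from = "score"
      )
      purrr::map_dfr(pairs, function(tp) {
        ok <- stats::complete.cases(sub[[tp[1]]], sub[[tp[2]]])
        res <- wilcoxon_signed_rank(sub[[tp[1]]][ok], sub[[tp[2]]][ok])
        tibble::tibble(
          scale = sc, from = tp[1], to = tp[2],
          n_pairs = sum(ok), statistic = res$statistic,
          p_value = res$p_value, method = res$method
        )
      })
    }
  )
  list(
    pairwise = pairwise,
    summary = trajectory_summary(
      dplyr::filter(scores, .data$timepoint %in% timepoints)
    )
  )
}
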