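# Independent reference implementations used as oracles.  All deliberately
# brute-force: explicit sums, full enumeration, hand rank construction.

# Two-way ANOVA mean squares from explicit group means, then ICC(2,1).
anova_icc_oracle <- function(test, retest) {
  x <- cbind(test, retest)
  n <- nrow(x)
  k <- ncol(x)
  grand <- sum(x) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) {
    ss_rows <- ss_rows + k * (sum(x[i, ]) / k - grand)^2
  }
  ss_cols <- 0
  for (j in seq_len(k)) {
    ss_cols <- ss_cols + n * (sum(x[, j]) / n - grand)^2
  }
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_tot <- ss_tot + (x[i, j] - grand)^2
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# Spreadsheet-style Cronbach alpha: per-column variances and row-sum variance.
alpha_oracle <- function(m) {
  k <- ncol(m)
  totals <- rowSums(m)
  vt <- sum((totals - mean(totals))^2) / (nrow(m) - 1)
  vi <- numeric(k)
  for (j in seq_len(k)) {
    vi[j] <- sum((m[, j] - mean(m[, j]))^2) / (nrow(m) - 1)
  }
  k / (k - 1) * (1 - sum(vi) / vt)
}

# Trapezoidal area under the empirical ROC (sensitivity vs 1-specificity),
# sweeping every observed threshold; classify diseased when score <= t.
trapezoid_auc_oracle <- function(diseased, healthy) {
  ts <- sort(unique(c(diseased, healthy)))
  sens <- vapply(ts, function(t) mean(diseased <= t), numeric(1))
  fpr <- vapply(ts, function(t) mean(healthy <= t), numeric(1))
  sens <- c(0, sens)
  fpr <- c(0, fpr)
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# Exact two-sided signed-rank p by enumerating every sign assignment.
wilcoxon_enum_oracle <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(v = NA_real_, p = 1))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (abs(w - mu) >= abs(v - mu) - 1e-9) count <- count + 1L
  }
  list(v = v, p = count / 2^n)
}

# Mid-ranks built by hand (mean of sorted positions per tied value), then
# Pearson correlation via explicit sums.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- mean(which(sort(v) == v[i]))
    }
    out
  }
  rx <- midrank(x)
  ry <- midrank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Build a one-sheet response table from a named value vector (or a single
# value recycled over all 34 items).
make_sheet <- function(values, subject = "s1", timepoint = "T0") {
  inst <- bhsii_instrument()
  if (length(values) == 1 && is.null(names(values))) {
    values <- stats::setNames(rep(values, nrow(inst)), inst$item_id)
  }
  tibble::tibble(
    subject_id = subject, timepoint = timepoint,
    item_id = names(values), value = as.integer(values)
  )
}

random_sheet <- function(subject = "s1", timepoint = "T0") {
  inst <- bhsii_instrument()
  make_sheet(stats::setNames(sample(0:4, nrow(inst), replace = TRUE),
                             inst$item_id),
             subject, timepoint)
}
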