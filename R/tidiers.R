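#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy bhsii_icc
#' @export
tidy.bhsii_icc <- function(x, ...) {
  tibble::tibble(
    term = c("between_subject", "between_administration", "residual"),
    mean_square = c(x$ms_rows, x$ms_cols, x$ms_error),
    df = c(x$n_subjects - 1,
           x$n_administrations - 1,
           (x$n_subjects - 1) * (x$n_administrations - 1))
  )
}

#' @method glance bhsii_icc
#' @export
glance.bhsii_icc <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, type = x$type, model = x$model_label,
    n_subjects = x$n_subjects, n_administrations = x$n_administrations,
    ms_between_subject = x$ms_rows,
    ms_between_administration = x$ms_cols,
    ms_residual = x$ms_error,
    reliable = x$reliable
  )
}

#' @method tidy bhsii_alpha
#' @export
tidy.bhsii_alpha <- function(x, ...) {
  tibble::tibble(
    item = names(x$item_variances),
    variance = unname(x$item_variances)
  )
}

#' @method glance bhsii_alpha
#' @export
glance.bhsii_alpha <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, k = x$k, n = x$n,
    total_variance = x$total_variance, consistent = x$consistent
  )
}

#' @method tidy bhsii_roc
#' @export
tidy.bhsii_roc <- function(x, ...) x$curve

#' @method glance bhsii_roc
#' @export
glance.bhsii_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    accuracy_flag = x$accuracy_flag,
    n_diseased = x$n_diseased, n_healthy = x$n_healthy,
    separable = x$separable,
    separating_lower = x$separating_lower,
    separating_upper = x$separating_upper,
    threshold = x$threshold,
    threshold_criterion = x$threshold_criterion,
    sensitivity = x$sensitivity,
    sensitivity_lower = x$sensitivity_ci[1],
    sensitivity_upper = x$sensitivity_ci[2],
    specificity = x$specificity,
    specificity_lower = x$specificity_ci[1],
    specificity_upper = x$specificity_ci[2],
    conf_level = x$conf_level
  )
}

#' @method tidy bhsii_validation
#' @export
tidy.bhsii_validation <- function(x, ...) {
  x$reliability
}

#' @method glance bhsii_validation
#' @export
glance.bhsii_validation <- function(x, ...) {
  tibble::tibble(
    n_cg_sheets = x$counts$n_sheets[x$counts$group == "CG"],
    n_sg_sheets = x$counts$n_sheets[x$counts$group == "SG"],
    icc_total = x$reliability$icc[x$reliability$scale == "total"],
    alpha_oq_t0 = if (!is.null(x$internal_consistency)) {
      x$internal_consistency$alpha
    } else NA_real_,
    auc = if (!is.null(x$roc)) x$roc$auc else NA_real_,
    n_skipped = length(x$skipped)
  )
}
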