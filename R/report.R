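#' Run the full BHSII validation pipeline on a cohort
#'
#' Orchestrates, in order: test-retest reliability (ICC per scale on the
#' control group's two administrations), internal consistency (Cronbach's
#' alpha over the 24 owner-questionnaire items at T0), construct validity
#' (ROC of surgical-at-T0 versus control total scores; Spearman matrix of
#' all scales at T0), and responsiveness (pairwise Wilcoxon over
#' timepoints, Kruskal--Wallis across age groups per timepoint,
#' chi-squared sex and limb demographics).  Analyses whose inputs are
#' degenerate (too few subjects, constant scores) are recorded as skip
#' entries rather than failing the run.
#'
#' @param cohort A `bhsii_cohort` (simulated or read from disk).
#' @param missing Missing-answer policy for scoring.
#' @param icc_type ICC form, `"agreement"` (ICC(2,1), default) or
#'   `"consistency"` (ICC(3,1)).
#' @param holm Apply a Holm adjustment to the pairwise longitudinal
#'   Wilcoxon p-values within each scale (off by default; the unadjusted
#'   per-pair tests are always retained).
#' @param verbose Emit one progress line per pipeline stage.
#' @return A list of class `bhsii_validation` with elements `counts`,
#'   `reliability`, `internal_consistency`, `roc`, `correlations`,
#'   `longitudinal`, `group_comparisons`, `demographics`, `summary`,
#'   `skipped` and `options`.
#' @export
run_validation <- function(cohort, missing = c("strict", "prorate"),
                           icc_type = c("agreement", "consistency"),
                           holm = FALSE, verbose = FALSE) {
  missing <- match.arg(missing)
  icc_type <- match.arg(icc_type)
  stopifnot(inherits(cohort, "bhsii_cohort"))
  say <- function(...) if (verbose) message("[bhsii] ", ...)
  skipped <- list()
  skip <- function(stage, e) {
    skipped[[stage]] <<- conditionMessage(e)
    NULL
  }

  meta <- cohort$metadata
  cg_ids <- meta$subject_id[meta$group == "CG"]
  sg_ids <- meta$subject_id[meta$group == "SG"]
  say("scoring ", length(unique(cohort$responses$subject_id)), " subjects")
  scores <- score_responses(cohort$responses, missing = missing)
  cg_scores <- dplyr::filter(scores, .data$subject_id %in% cg_ids)
  sg_scores <- dplyr::filter(scores, .data$subject_id %in% sg_ids)

  counts <- dplyr::distinct(scores, .data$subject_id, .data$timepoint) |>
    dplyr::mutate(group = ifelse(.data$subject_id %in% cg_ids, "CG", "SG")) |>
    dplyr::count(.data$group, name = "n_sheets")

  ## --- reliability -------------------------------------------------------
  say("test-retest reliability on ", length(cg_ids), " control subjects")
  cg_wide <- scores_wide(cg_scores)
  reliability <- purrr::map_dfr(bhsii_scales(), function(sc) {
    res <- tryCatch({
      tw <- tidyr::pivot_wider(
        dplyr::filter(cg_scores, .data$scale == sc) |>
          dplyr::select("subject_id", "timepoint", "score"),
        names_from = "timepoint", values_from = "score"
      )
      icc_test_retest(tw$test, tw$retest, type = icc_type)
    }, bhsii_degenerate_error = function(e) skip(paste0("icc_", sc), e))
    if (is.null(res)) {
      return(tibble::tibble(scale = sc, icc = NA_real_))
    }
    dplyr::mutate(glance(res), scale = sc, .before = 1)
  })

  alpha <- tryCatch({
    inst <- bhsii_instrument()
    oq_items <- inst$item_id[inst$section == "OQ"]
    mat <- cohort$responses |>
      dplyr::filter(.data$subject_id %in% sg_ids, .data$timepoint == "T0",
                    .data$item_id %in% oq_items) |>
      tidyr::pivot_wider(names_from = "item_id", values_from = "value") |>
      dplyr::select(dplyr::all_of(oq_items))
    cronbach_alpha(mat)
  }, bhsii_degenerate_error = function(e) skip("cronbach_alpha", e))
  say("Cronbach alpha on 24 OQ items at T0")

  ## --- construct validity ------------------------------------------------
  sg_t0_wide <- scores_wide(dplyr::filter(sg_scores, .data$timepoint == "T0"))
  cg_test_wide <- scores_wide(
    dplyr::filter(cg_scores, .data$timepoint == "test")
  )
  roc <- tryCatch(
    roc_analysis(sg_t0_wide$total, cg_test_wide$total),
    bhsii_degenerate_error = function(e) skip("roc", e),
    bhsii_validation_error = function(e) skip("roc", e)
  )
  say("ROC: ", nrow(sg_t0_wide), " diseased vs ", nrow(cg_test_wide),
      " healthy totals")

  correlations <- tryCatch(
    spearman_matrix(
      dplyr::select(sg_t0_wide, -"subject_id", -"timepoint")
    ),
    bhsii_validation_error = function(e) skip("correlations", e)
  )
  say("Spearman matrix over ", length(bhsii_scales()), " scales at T0")

  ## --- responsiveness ----------------------------------------------------
  longitudinal <- tryCatch(
    longitudinal_tests(sg_scores),
    bhsii_degenerate_error = function(e) skip("longitudinal", e)
  )
  if (!is.null(longitudinal) && holm) {
    longitudinal$pairwise <- longitudinal$pairwise |>
      dplyr::group_by(.data$scale) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }
  say("pairwise Wilcoxon over timepoints")

  sg_meta <- dplyr::filter(meta, .data$group == "SG")
  sg_with_age <- dplyr::left_join(
    scores_wide(sg_scores),
    dplyr::select(sg_meta, "subject_id", "age_group"),
    by = "subject_id"
  )
  group_comparisons <- purrr::map_dfr(
    intersect(c("T0", "T1", "T3", "T6"), unique(sg_with_age$timepoint)),
    function(tp) {
      sub <- dplyr::filter(sg_with_age, .data$timepoint == tp)
      purrr::map_dfr(bhsii_scales(), function(sc) {
        res <- tryCatch(
          kruskal_wallis(sub[[sc]], sub$age_group),
          bhsii_validation_error = function(e) {
            skip(paste0("kruskal_", sc, "_", tp), e)
          }
        )
        if (is.null(res)) {
          return(tibble::tibble(timepoint = tp, scale = sc))
        }
        dplyr::mutate(dplyr::select(res, -"group_n"),
                      timepoint = tp, scale = sc, .before = 1)
      })
    }
  )
  say("Kruskal-Wallis across age groups per timepoint")

  demographics <- purrr::map_dfr(c("sex", "limb"), function(v) {
    tab <- table(meta$group, meta[[v]])
    res <- tryCatch(
      chi_square_independence(tab),
      bhsii_validation_error = function(e) skip(paste0("chisq_", v), e)
    )
    if (is.null(res)) return(tibble::tibble(variable = v))
    dplyr::mutate(res, variable = v, .before = 1)
  })
  say("demographic chi-squared tests")

  summary <- tryCatch(
    trajectory_summary(sg_scores),
    bhsii_degenerate_error = function(e) skip("summary", e)
  )

  structure(
    list(
      counts = counts,
      reliability = reliability,
      internal_consistency = alpha,
      roc = roc,
      correlations = correlations,
      longitudinal = longitudinal,
      group_comparisons = group_comparisons,
      demographics = demographics,
      summary = summary,
      skipped = skipped,
      options = list(
        missing = missing, icc_type = icc_type, holm = holm,
        seed = cohort$seed,
        notes = c(
          "Spearman p-values: t-approximation, no multiple-testing correction across the matrix",
          "pairwise Wilcoxon over timepoints uncorrected unless holm = TRUE",
          "Wilcoxon zero differences discarded; ties mid-ranked"
        )
      )
    ),
    class = "bhsii_validation"
  )
}

#' @export
print.bhsii_validation <- function(x, ...) {
  cat("<bhsii_validation>\n")
  cat("  sheets: ", paste0(x$counts$group, "=", x$counts$n_sheets,
                           collapse = ", "), "\n", sep = "")
  if (!is.null(x$reliability)) {
    icc_tot <- x$reliability$icc[x$reliability$scale == "total"]
    cat("  ICC(total): ", format(round(icc_tot, 3)), "\n", sep = "")
  }
  if (!is.null(x$internal_consistency)) {
    cat("  Cronbach alpha (OQ, T0): ",
        format(round(x$internal_consistency$alpha, 3)), "\n", sep = "")
  }
  if (!is.null(x$roc)) {
    cat("  AUC: ", format(round(x$roc$auc, 3)), "\n", sep = "")
  }
  if (length(x$skipped) > 0) {
    cat("  skipped: ", paste(names(x$skipped), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Deterministic rendering: the same report always produces the same
#' bytes.  Every statistic is labelled with its method variant (ICC form,
#' tie handling, threshold criterion).
#'
#' @param report A `bhsii_validation`.
#' @param path Destination file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_validation_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "bhsii_validation"))
  payload <- list(
    counts = report$counts,
    reliability = report$reliability,
    internal_consistency = if (!is.null(report$internal_consistency)) {
      glance(report$internal_consistency)
    },
    roc = if (!is.null(report$roc)) glance(report$roc),
    correlations = report$correlations,
    longitudinal_pairwise = if (!is.null(report$longitudinal)) {
      report$longitudinal$pairwise
    },
    group_comparisons = report$group_comparisons,
    demographics = report$demographics,
    summary = report$summary,
    skipped = report$skipped,
    options = report$options
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}

#' Render a median (IQR) follow-up table
#'
#' One row per scale, one column per timepoint, each cell
#' `median (q1-q3)` to two decimals -- the conventional presentation of
#' follow-up score tables.
#'
#' @param x A `bhsii_validation`, a `bhsii_cohort`, or a
#'   [trajectory_summary()] tibble.
#' @param format `"tibble"` (default), `"md"` (markdown lines) or `"csv"`
#'   (CSV lines).
#' @return A tibble or a character vector of rendered lines.
#' @export
report_table <- function(x, format = c("tibble", "md", "csv")) {
  format <- match.arg(format)
  summary <- if (inherits(x, "bhsii_validation")) {
    x$summary
  } else if (inherits(x, "bhsii_cohort")) {
    trajectory_summary(x)
  } else {
    x
  }
  cells <- summary |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f-%.2f)",
                                 .data$median, .data$q1, .data$q3)) |>
    dplyr::select("scale", "timepoint", "cell") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "cell")
  if (format == "tibble") return(cells)
  if (format == "csv") {
    return(readr::format_csv(cells) |> strsplit("\n") |> unlist())
  }
  header <- paste0("| ", paste(names(cells), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, sep, rows)
}
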