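#' Score BHSII response sheets
#'
#' Computes raw sums and normalized 0--100 scores for every administration
#' (subject x timepoint) in a long-format response table.  Each domain is
#' normalized as `100 - raw * 100 / max_raw`, so 100 means absence of any
#' stifle problem and 0 the most severe presentation.  Section scores
#' (`oq`: Pain + Stiffness + Function, max raw 96; `cr`: Visual + Manual,
#' max raw 40) and the full index (`total`, max raw 136) use the same
#' formula on the pooled raw sums.
#'
#' @param responses Long table with columns `subject_id`, `timepoint`,
#'   `item_id`, `value` (integers 0--4; `NA` or absent rows are missing
#'   answers).
#' @param instrument Item table, see [bhsii_instrument()].
#' @param missing Missing-answer policy. `"strict"` (default) rejects any
#'   incomplete sheet with an error naming the missing items.  `"prorate"`
#'   follows the KOOS convention: a domain with at least half of its items
#'   answered is scored by substituting the mean of the answered items;
#'   with fewer answers the domain -- and every aggregate containing it --
#'   is `NA`.
#' @return A tibble with one row per (subject, timepoint, scale):
#'   `subject_id`, `timepoint`, `scale` (factor: `pain`, `stiffness`,
#'   `function`, `visual`, `manual`, `oq`, `cr`, `total`), `n_items`,
#'   `n_answered`, `raw`, `max_raw`, `score`.
#' @examples
#' inst <- bhsii_instrument()
#' sheet <- tibble::tibble(
#'   subject_id = "d1", timepoint = "T0",
#'   item_id = inst$item_id, value = 1L
#' )
#' score_responses(sheet) # total raw 34, total score 75
#' @export
score_responses <- function(responses, instrument = bhsii_instrument(),
                            missing = c("strict", "prorate")) {
  missing <- match.arg(missing)
  responses <- validate_responses(responses, instrument)

  # Expand to the full item grid so absent rows become explicit NAs.
  grid <- tidyr::expand_grid(
    dplyr::distinct(responses, .data$subject_id, .data$timepoint),
    item_id = instrument$item_id
  )
  full <- dplyr::left_join(
    grid, responses,
    by = c("subject_id", "timepoint", "item_id")
  )
  full <- dplyr::left_join(
    full,
    dplyr::select(instrument, "item_id", "domain_code"),
    by = "item_id"
  )

  if (missing == "strict") {
    miss <- dplyr::filter(full, is.na(.data$value))
    if (nrow(miss) > 0) {
      detail <- paste0(
        "subject ", miss$subject_id, " (", miss$timepoint, "): item ",
        miss$item_id
      )
      stop_missing(paste0(
        nrow(miss), " missing answer(s) under policy 'strict':\n",
        paste0("  - ", utils::head(detail, 20L), collapse = "\n"),
        if (nrow(miss) > 20) "\n  - ..."
      ))
    }
  }

  domains <- full |>
    dplyr::group_by(.data$subject_id, .data$timepoint, .data$domain_code) |>
    dplyr::summarise(
      n_items    = dplyr::n(),
      n_answered = sum(!is.na(.data$value)),
      raw = prorated_raw(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scale   = scale_of_domain(.data$domain_code),
      max_raw = 4L * .data$n_items
    )

  section_of <- c(pain = "oq", stiffness = "oq", `function` = "oq",
                  visual = "cr", manual = "cr")
  aggregates <- function(tbl, scale_name, members) {
    tbl |>
      dplyr::filter(.data$scale %in% members) |>
      dplyr::group_by(.data$subject_id, .data$timepoint) |>
      dplyr::summarise(
        n_items    = sum(.data$n_items),
        n_answered = sum(.data$n_answered),
        raw        = sum(.data$raw),   # NA propagates from undefined domains
        max_raw    = sum(.data$max_raw),
        .groups = "drop"
      ) |>
      dplyr::mutate(scale = scale_name)
  }
  oq  <- aggregates(domains, "oq", names(section_of)[section_of == "oq"])
  cr  <- aggregates(domains, "cr", names(section_of)[section_of == "cr"])
  tot <- aggregates(domains, "total", names(section_of))

  out <- dplyr::bind_rows(
    dplyr::select(domains, -"domain_code"), oq, cr, tot
  ) |>
    dplyr::mutate(
      scale = factor(.data$scale, levels = bhsii_scales()),
      score = 100 - .data$raw * 100 / .data$max_raw
    ) |>
    dplyr::arrange(.data$subject_id, .data$timepoint, .data$scale) |>
    dplyr::select(
      "subject_id", "timepoint", "scale", "n_items", "n_answered",
      "raw", "max_raw", "score"
    )
  out
}

# KOOS-style proration: mean of answered items substituted for the missing
# ones when at least half the domain is answered, else undefined.
prorated_raw <- function(values) {
  k <- length(values)
  answered <- sum(!is.na(values))
  if (answered == k) return(sum(values))
  if (answered >= k / 2) return(mean(values, na.rm = TRUE) * k)
  NA_real_
}

#' Score a single BHSII domain
#'
#' Raw sum and normalized score for one domain across all administrations
#' in a response table.
#'
#' @inheritParams score_responses
#' @param domain_code One of `"P"`, `"S"`, `"F"`, `"V"`, `"M"`.
#' @return A tibble with one row per (subject, timepoint): `subject_id`,
#'   `timepoint`, `raw`, `score`.
#' @export
score_domain <- function(responses, domain_code,
                         instrument = bhsii_instrument(),
                         missing = c("strict", "prorate")) {
  domain_code <- match.arg(domain_code, c("P", "S", "F", "V", "M"))
  items <- dplyr::filter(instrument, .data$domain_code == !!domain_code)
  sub <- dplyr::filter(responses, .data$item_id %in% items$item_id)
  scored <- score_responses(sub, instrument = items, missing = missing)
  scored |>
    dplyr::filter(.data$scale == scale_of_domain(domain_code)) |>
    dplyr::select("subject_id", "timepoint", "raw", "score")
}

#' Pivot long scores to one column per scale
#'
#' @param scores Output of [score_responses()].
#' @return A tibble with one row per (subject, timepoint) and one column of
#'   normalized scores per scale.
#' @export
scores_wide <- function(scores) {
  tidyr::pivot_wider(
    dplyr::select(scores, "subject_id", "timepoint", "scale", "score"),
    names_from = "scale", values_from = "score"
  )
}

stop_missing <- function(msg) {
  stop(structure(
    class = c("bhsii_missing_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
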