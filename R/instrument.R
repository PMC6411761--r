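#' The BHSII instrument definition
#'
#' Builds the canonical item table of the Bologna Healing Stifle Injury
#' Index (BHSII): 34 five-level Likert items (scored 0--4, 0 = never,
#' 4 = always) split between an owner questionnaire (OQ) and a clinical
#' record (CR).  The OQ holds three domains -- Pain (P1--P12), Stiffness
#' (S1--S5) and Function (F1--F7) -- and the CR two: Visual examination
#' (V1--V3) and Manual examination (M1--M7).
#'
#' Item prompts are stored as metadata placeholders; scoring never depends
#' on prompt wording.
#'
#' @return A tibble of class `bhsii_instrument` with one row per item and
#'   columns `item_id`, `domain_code`, `domain`, `section`, `prompt`,
#'   `min_value`, `max_value`.
#' @examples
#' inst <- bhsii_instrument()
#' nrow(inst)          # 34
#' bhsii_domains(inst) # per-domain item counts and raw maxima
#' @export
bhsii_instrument <- function() {
  spec <- tibble::tribble(
    ~domain_code, ~domain,              ~section, ~n_items,
    "P",          "Pain",               "OQ",     12L,
    "S",          "Stiffness",          "OQ",      5L,
    "F",          "Function",           "OQ",      7L,
    "V",          "Visual examination", "CR",      3L,
    "M",          "Manual examination", "CR",      7L
  )
  items <- tidyr::uncount(spec, .data$n_items, .id = "item_no")
  items <- dplyr::mutate(
    items,
    item_id   = paste0(.data$domain_code, .data$item_no),
    prompt    = paste0("Placeholder prompt for item ", .data$item_id),
    min_value = 0L,
    max_value = 4L
  )
  out <- dplyr::select(
    items, "item_id", "domain_code", "domain", "section",
    "prompt", "min_value", "max_value"
  )
  class(out) <- c("bhsii_instrument", class(out))
  out
}

#' Summarise an instrument by domain
#'
#' @param instrument An item table from [bhsii_instrument()].
#' @return A tibble with one row per domain: `domain_code`, `domain`,
#'   `section`, `n_items` and `max_raw` (the maximum raw sum, item count
#'   times 4).
#' @export
bhsii_domains <- function(instrument = bhsii_instrument()) {
  instrument |>
    dplyr::group_by(.data$domain_code, .data$domain, .data$section) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      max_raw = sum(.data$max_value),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$domain_code, c("P", "S", "F", "V", "M")))
}

# Ordered scale vocabulary used by the scoring and reporting layers.
# Five domains, the two sections, and the full index.
bhsii_scales <- function() {
  c("pain", "stiffness", "function", "visual", "manual", "oq", "cr", "total")
}

scale_of_domain <- function(domain_code) {
  c(P = "pain", S = "stiffness", F = "function",
    V = "visual", M = "manual")[domain_code]
}

timepoint_levels <- function() c("T0", "T1", "T3", "T6", "test", "retest")

#' Validate a long-format response table
#'
#' Checks a table of item responses (one row per subject, timepoint and
#' item) against an instrument definition: known item ids, integer values
#' within each item's 0--4 bounds, a closed timepoint vocabulary
#' (`T0`,`T1`,`T3`,`T6`,`test`,`retest`) and no duplicated
#' (subject, timepoint, item) triples.
#'
#' @param responses Data frame with columns `subject_id`, `timepoint`,
#'   `item_id`, `value`.
#' @param instrument Item table, see [bhsii_instrument()].
#' @return `responses` as a tibble, invisibly validated; an error of class
#'   `bhsii_validation_error` describes every offending row otherwise.
#' @export
validate_responses <- function(responses, instrument = bhsii_instrument()) {
  required <- c("subject_id", "timepoint", "item_id", "value")
  missing_cols <- setdiff(required, names(responses))
  if (length(missing_cols) > 0) {
    stop_validation(paste0(
      "responses table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  responses <- tibble::as_tibble(responses)
  responses$value <- suppressWarnings(as.numeric(responses$value))
  rows <- seq_len(nrow(responses))

  problems <- character(0)
  unknown <- !(responses$item_id %in% instrument$item_id)
  if (any(unknown)) {
    problems <- c(problems, paste0(
      "row ", rows[unknown], ": unknown item_id '",
      responses$item_id[unknown], "'"
    ))
  }
  bad_tp <- !(responses$timepoint %in% timepoint_levels())
  if (any(bad_tp)) {
    problems <- c(problems, paste0(
      "row ", rows[bad_tp], ": unknown timepoint '",
      responses$timepoint[bad_tp], "'"
    ))
  }
  bounds <- instrument[match(responses$item_id, instrument$item_id), ]
  present <- !is.na(responses$value) & !unknown
  non_int <- present & responses$value != round(responses$value)
  out_rng <- present & !non_int &
    (responses$value < bounds$min_value | responses$value > bounds$max_value)
  if (any(non_int)) {
    problems <- c(problems, paste0(
      "row ", rows[non_int], ": non-integer value ", responses$value[non_int],
      " for item ", responses$item_id[non_int]
    ))
  }
  if (any(out_rng)) {
    problems <- c(problems, paste0(
      "row ", rows[out_rng], ": value ", responses$value[out_rng],
      " for item ", responses$item_id[out_rng], " outside [",
      bounds$min_value[out_rng], ", ", bounds$max_value[out_rng], "]"
    ))
  }
  key <- paste(responses$subject_id, responses$timepoint, responses$item_id)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems, paste0(
      "row ", rows[dup], ": duplicate (subject, timepoint, item) triple '",
      key[dup], "'"
    ))
  }
  if (length(problems) > 0) {
    stop_validation(paste0(
      length(problems), " invalid response row(s):\n",
      paste0("  - ", problems, collapse = "\n")
    ))
  }
  responses$value <- as.integer(responses$value)
  responses
}

stop_validation <- function(msg) {
  stop(structure(
    class = c("bhsii_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_degenerate <- function(msg) {
  stop(structure(
    class = c("bhsii_degenerate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
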