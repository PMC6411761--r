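#' Read a long-format response CSV
#'
#' Dialect: comma-separated UTF-8 with header
#' `subject_id,timepoint,item_id,value`; an empty `value` field is a
#' missing answer.  Every row is validated (known item, closed timepoint
#' vocabulary, integer value within the item's bounds, no duplicate
#' (subject, timepoint, item) triples); offending rows are reported with
#' their positions.
#'
#' @param path CSV file path.
#' @param instrument Item table, see [bhsii_instrument()].
#' @return A validated long response tibble.
#' @export
read_responses <- function(path, instrument = bhsii_instrument()) {
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timepoint = readr::col_character(),
      item_id = readr::col_character(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
  validate_responses(raw, instrument)
}

#' Write responses to the long-format CSV dialect
#'
#' @param responses Long response tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(
    dplyr::select(responses, "subject_id", "timepoint", "item_id", "value"),
    path, na = ""
  )
  invisible(path)
}

#' Read a cohort metadata CSV
#'
#' @param path CSV with columns `subject_id`, `group`, `age_group`, `age`,
#'   `weight`, `sex`, `limb` (and optionally `t6_dropout`).
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group", "age_group", "age", "weight",
                "sex", "limb")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop_validation(paste0(
      "metadata lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  meta
}

#' Write a synthetic cohort to disk
#'
#' Writes `metadata.csv`, `responses.csv` (instrument CSV dialect) and
#' `health.csv` (the latent truth, for checking recovery) into a
#' directory.
#'
#' @param cohort A `bhsii_cohort` from [simulate_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bhsii_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"), na = "")
  write_responses(cohort$responses, file.path(dir, "responses.csv"))
  readr::write_csv(cohort$health, file.path(dir, "health.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `metadata.csv` and `responses.csv`
#'   (`health.csv` is read when present).
#' @return A `bhsii_cohort` (without a config).
#' @export
read_cohort <- function(dir) {
  metadata <- read_metadata(file.path(dir, "metadata.csv"))
  responses <- read_responses(file.path(dir, "responses.csv"))
  health_path <- file.path(dir, "health.csv")
  health <- if (file.exists(health_path)) {
    readr::read_csv(health_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  structure(
    list(metadata = metadata, responses = responses, health = health,
         config = NULL, seed = NA_integer_),
    class = "bhsii_cohort"
  )
}
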