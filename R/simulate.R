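#' Configuration for the synthetic BHSII cohort generator
#'
#' Defines the study design the simulator emulates: a control group of
#' healthy dogs administered the instrument twice two weeks apart, and a
#' surgical group followed at diagnosis (T0) and 1, 3 and 6 months after
#' cranial cruciate ligament surgery (T1, T3, T6), with part of the
#' surgical group lost to follow-up at T6.
#'
#' Item responses follow a thresholded-Gaussian ordinal model.  Subject
#' `i` at timepoint `t` carries a latent health `h` in \[0,1\] drawn from
#' `Normal(mean_t, sd_t)` (plus `age_group_t0_shift` for age group A at
#' T0) and a stable subject factor `u ~ N(0, subject_factor_sd^2)` shared
#' across items, which induces inter-item correlation.  Item `j` scores
#' `round(clamp(4 * (1 - h) + loading_j * u + e, 0, 4))` with
#' `e ~ N(0, item_noise_sd^2)`.  Retest sheets reuse `h` and `u` and
#' redraw only `e` with `retest_noise_sd`.
#'
#' @param n_control Healthy control dogs (two administrations each).
#' @param n_surgical Surgical dogs (administrations at T0/T1/T3, T6 unless
#'   dropped out).
#' @param n_t6_dropout Surgical dogs missing the T6 administration.
#' @param health_by_time Tibble with columns `timepoint`, `mean`, `sd`:
#'   latent-health distribution per follow-up timepoint.
#' @param control_health Length-2 numeric `(mean, sd)` of control latent
#'   health.
#' @param subject_factor_sd Standard deviation of the stable subject
#'   factor `u` (score units on the 0--4 item scale).
#' @param item_noise_sd Standard deviation of per-item measurement noise
#'   at a regular administration.
#' @param retest_noise_sd Standard deviation of per-item noise at the
#'   control retest administration.
#' @param item_loadings Named numeric vector (one entry per item id)
#'   scaling the subject factor per item; defaults give clinician items a
#'   somewhat higher loading than owner items, reflecting the greater
#'   consistency of a trained examiner.
#' @param age_group_t0_shift Additive latent-health bonus for age group A
#'   (youngest dogs) at T0 only.
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return A list of class `bhsii_config`.
#' @export
cohort_config <- function(n_control = 20L,
                          n_surgical = 158L,
                          n_t6_dropout = 77L,
                          health_by_time = tibble::tibble(
                            timepoint = c("T0", "T1", "T3", "T6"),
                            mean = c(0.50, 0.78, 0.92, 0.96),
                            sd   = c(0.12, 0.08, 0.05, 0.04)
                          ),
                          control_health = c(0.97, 0.02),
                          subject_factor_sd = 1.0,
                          item_noise_sd = 1.0,
                          retest_noise_sd = 0.25,
                          item_loadings = default_loadings(),
                          age_group_t0_shift = 0.08,
                          seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control),
    n_surgical = as.integer(n_surgical),
    n_t6_dropout = as.integer(n_t6_dropout),
    health_by_time = tibble::as_tibble(health_by_time),
    control_health = as.numeric(control_health),
    subject_factor_sd = as.numeric(subject_factor_sd),
    item_noise_sd = as.numeric(item_noise_sd),
    retest_noise_sd = as.numeric(retest_noise_sd),
    item_loadings = item_loadings,
    age_group_t0_shift = as.numeric(age_group_t0_shift),
    seed = as.integer(seed)
  )
  class(cfg) <- "bhsii_config"
  validate_config(cfg)
}

# Per-domain loadings on the shared subject factor, weighted inversely to
# item count so every domain keeps usable between-subject variance at the
# domain-score level, and higher for clinician domains (a trained examiner
# rates stable dog traits more consistently than an owner).  A mild
# within-domain spread avoids perfectly parallel items.
default_loadings <- function(instrument = bhsii_instrument()) {
  base <- c(P = 0.70, S = 0.95, F = 0.82,
            V = 1.80, M = 1.28)[instrument$domain_code]
  spread <- stats::ave(
    seq_len(nrow(instrument)), instrument$domain_code,
    FUN = function(i) seq(-0.1, 0.1, length.out = length(i))
  )
  stats::setNames(base + spread, instrument$item_id)
}

validate_config <- function(cfg) {
  bad <- function(msg) {
    stop(structure(
      class = c("bhsii_config_error", "error", "condition"),
      list(message = msg, call = NULL)
    ))
  }
  if (cfg$n_control < 1 || cfg$n_surgical < 1) bad("group sizes must be >= 1")
  if (cfg$n_t6_dropout < 0 || cfg$n_t6_dropout >= cfg$n_surgical) {
    bad("n_t6_dropout must be in [0, n_surgical)")
  }
  sds <- c(cfg$subject_factor_sd, cfg$item_noise_sd, cfg$retest_noise_sd,
           cfg$health_by_time$sd, cfg$control_health[2])
  if (any(sds < 0) || anyNA(sds)) bad("all standard deviations must be >= 0")
  if (!all(c("timepoint", "mean", "sd") %in% names(cfg$health_by_time))) {
    bad("health_by_time needs columns timepoint, mean, sd")
  }
  cfg$health_by_time$mean <- pmin(pmax(cfg$health_by_time$mean, 0), 1)
  cfg$control_health[1] <- min(max(cfg$control_health[1], 0), 1)
  inst <- bhsii_instrument()
  if (!all(inst$item_id %in% names(cfg$item_loadings))) {
    bad("item_loadings must name every instrument item")
  }
  cfg
}

#' Simulate a synthetic validation cohort
#'
#' Generates metadata, item responses and the underlying latent health for
#' a control group (CG, administrations `test`/`retest`) and a surgical
#' group (SG, timepoints T0/T1/T3 and T6 for non-dropouts) under the
#' ordinal response model described in [cohort_config()].  Covariates
#' (weight, sex, limb, age) are drawn to echo a realistic caseload but --
#' apart from the age-group A baseline shift -- have no effect on
#' responses.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; overrides `config$seed` when given.  The same
#'   seed reproduces the cohort bit for bit.
#' @return A list of class `bhsii_cohort`: `metadata` (subject_id, group,
#'   age_group, age, weight, sex, limb, t6_dropout), `responses` (long
#'   item table), `health` (latent health per sheet) and `config`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' dplyr::count(cohort$responses, subject_id, timepoint) |> nrow() # 595 sheets
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))

  inst <- bhsii_instrument()
  lambda <- config$item_loadings[inst$item_id]
  n_items <- nrow(inst)

  ## --- metadata ----------------------------------------------------------
  cg_ids <- sprintf("C%03d", seq_len(config$n_control))
  sg_ids <- sprintf("S%03d", seq_len(config$n_surgical))

  cg_meta <- tibble::tibble(
    subject_id = cg_ids,
    group = "CG",
    age_group = NA_character_,
    age = round(truncnorm(config$n_control, 5.8, 3.3, lower = 0.5), 1),
    weight = round(truncnorm(config$n_control, 23.4, 11.3, lower = 2), 1),
    sex = sample(c("M", "F"), config$n_control, replace = TRUE,
                 prob = c(4, 16) / 20),
    limb = "right",
    t6_dropout = FALSE
  )

  age_ranges <- list(A = c(0.5, 3), B = c(4, 6.9), C = c(7, 9), D = c(9.1, 14))
  sg_age_group <- sample(c("A", "B", "C", "D"), config$n_surgical,
                         replace = TRUE, prob = c(39, 40, 40, 39) / 158)
  sg_age <- vapply(sg_age_group, function(g) {
    round(stats::runif(1, age_ranges[[g]][1], age_ranges[[g]][2]), 1)
  }, numeric(1), USE.NAMES = FALSE)
  dropout_ids <- sort(sample(sg_ids, config$n_t6_dropout))
  sg_meta <- tibble::tibble(
    subject_id = sg_ids,
    group = "SG",
    age_group = sg_age_group,
    age = sg_age,
    weight = round(truncnorm(config$n_surgical, 29.2, 14.4, lower = 2), 1),
    sex = sample(c("M", "F"), config$n_surgical, replace = TRUE,
                 prob = c(65, 93) / 158),
    limb = sample(c("right", "left"), config$n_surgical, replace = TRUE),
    t6_dropout = sg_ids %in% dropout_ids
  )
  metadata <- dplyr::bind_rows(cg_meta, sg_meta)

  ## --- latent structure --------------------------------------------------
  u <- stats::rnorm(nrow(metadata), 0, config$subject_factor_sd)
  names(u) <- metadata$subject_id

  cg_health <- clamp01(stats::rnorm(
    config$n_control, config$control_health[1], config$control_health[2]
  ))
  health_cg <- tibble::tibble(
    subject_id = rep(cg_ids, times = 2),
    timepoint = rep(c("test", "retest"), each = config$n_control),
    health = rep(cg_health, times = 2)
  )

  hbt <- config$health_by_time
  health_sg <- tidyr::expand_grid(
    subject_id = sg_ids, timepoint = hbt$timepoint
  ) |>
    dplyr::left_join(hbt, by = "timepoint") |>
    dplyr::left_join(
      dplyr::select(sg_meta, "subject_id", "age_group", "t6_dropout"),
      by = "subject_id"
    )
  shift <- ifelse(
    health_sg$age_group == "A" & health_sg$timepoint == "T0",
    config$age_group_t0_shift, 0
  )
  health_sg$health <- clamp01(
    stats::rnorm(nrow(health_sg), health_sg$mean, health_sg$sd) + shift
  )
  health_sg <- health_sg |>
    dplyr::filter(!(.data$timepoint == "T6" & .data$t6_dropout)) |>
    dplyr::select("subject_id", "timepoint", "health")

  health <- dplyr::bind_rows(health_sg, health_cg)

  ## --- item responses ----------------------------------------------------
  noise_sd <- ifelse(health$timepoint == "retest",
                     config$retest_noise_sd, config$item_noise_sd)
  n_sheets <- nrow(health)
  eps <- matrix(stats::rnorm(n_sheets * n_items, 0,
                             rep(noise_sd, each = n_items)),
                nrow = n_items)
  latent <- 4 * (1 - rep(health$health, each = n_items)) +
    lambda * u[rep(health$subject_id, each = n_items)] + eps
  value <- as.integer(round(pmin(pmax(latent, 0), 4)))

  responses <- tibble::tibble(
    subject_id = rep(health$subject_id, each = n_items),
    timepoint = rep(health$timepoint, each = n_items),
    item_id = rep(inst$item_id, times = n_sheets),
    value = value
  )

  structure(
    list(metadata = metadata, responses = responses, health = health,
         config = config, seed = as.integer(seed)),
    class = "bhsii_cohort"
  )
}

#' @export
print.bhsii_cohort <- function(x, ...) {
  sheets <- dplyr::distinct(x$responses, .data$subject_id, .data$timepoint)
  n_cg <- sum(x$metadata$group == "CG")
  cat("<bhsii_cohort>\n")
  cat("  subjects: ", nrow(x$metadata), " (", n_cg, " CG, ",
      nrow(x$metadata) - n_cg, " SG)\n", sep = "")
  cat("  sheets:   ", nrow(sheets), "\n", sep = "")
  cat("  seed:     ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Median and interquartile range of scores per timepoint
#'
#' Complete-case per timepoint: each timepoint summarises the sheets
#' actually administered then.
#'
#' @param x A `bhsii_cohort` or a long score table from
#'   [score_responses()].
#' @param group When `x` is a cohort, which group to summarise (default
#'   the surgical group).
#' @param missing Missing-answer policy passed to [score_responses()].
#' @return A tibble with one row per (scale, timepoint): `n`, `median`,
#'   `q1`, `q3`.
#' @export
trajectory_summary <- function(x, group = "SG",
                               missing = c("strict", "prorate")) {
  missing <- match.arg(missing)
  scores <- if (inherits(x, "bhsii_cohort")) {
    ids <- x$metadata$subject_id[x$metadata$group %in% group]
    score_responses(
      dplyr::filter(x$responses, .data$subject_id %in% ids),
      missing = missing
    )
  } else {
    x
  }
  if (nrow(scores) == 0) {
    stop_degenerate("no sheets to summarise")
  }
  scores |>
    dplyr::group_by(.data$scale, .data$timepoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$score, na.rm = TRUE),
      q1 = unname(stats::quantile(.data$score, 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(.data$score, 0.75, na.rm = TRUE)),
      .groups = "drop"
    )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

truncnorm <- function(n, mean, sd, lower = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  }
  x
}
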