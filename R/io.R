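# CSV and JSON readers/writers for the file schemas shared with the CLI.

hi_read_csv <- function(path, what) {
  if (!file.exists(path)) {
    abort_validation(sprintf("%s file not found: %s", what, path))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a per-subject beat-to-beat blood pressure CSV
#'
#' Expected header `beat,time_s,sbp_mmhg` (`time_s` optional). The subject id
#' defaults to the file name without extension.
#'
#' @param path CSV path.
#' @param subject_id Override the subject id.
#' @return A validated tibble `subject_id`, `beat`, (`time_s`), `sbp_mmhg`.
#' @export
read_bp_csv <- function(path, subject_id = NULL) {
  df <- hi_read_csv(path, "beat-to-beat sBP")
  check_columns(df, c("beat", "sbp_mmhg"), sprintf("BP file %s", basename(path)))
  validate_beat_series(df)
  df$subject_id <- subject_id %||% tools::file_path_sans_ext(basename(path))
  tibble::as_tibble(df[c("subject_id", intersect(c("beat", "time_s", "sbp_mmhg"),
                                                 names(df)))])
}

#' Read a per-subject SART trial CSV
#'
#' Expected header `trial,digit,rt_ms`.
#'
#' @inheritParams read_bp_csv
#' @return A tibble `subject_id`, `trial`, `digit`, `rt_ms` (validation happens
#'   at scoring time, so malformed sessions can be itemised per subject).
#' @export
read_sart_csv <- function(path, subject_id = NULL) {
  df <- hi_read_csv(path, "SART trial log")
  check_columns(df, c("trial", "digit", "rt_ms"), sprintf("SART file %s", basename(path)))
  df$subject_id <- subject_id %||% tools::file_path_sans_ext(basename(path))
  tibble::as_tibble(df[c("subject_id", "trial", "digit", "rt_ms")])
}

#' Read a gait walk CSV
#'
#' Expected header `subject_id,walk1_cms[,walk2_cms]`.
#'
#' @param path CSV path.
#' @return A tibble with one row per subject.
#' @export
read_gait_csv <- function(path) {
  df <- hi_read_csv(path, "gait")
  check_columns(df, c("subject_id", "walk1_cms"), sprintf("gait file %s", basename(path)))
  tibble::as_tibble(df)
}

#' Read a cohort survival/covariate CSV
#'
#' Requires at least `subject_id`, `hi`, `followup_days`, `event`, `cause`;
#' covariates and competitor score columns pass through. Enforces the
#' outcome invariants: positive follow-up, event in \{0, 1\}, and
#' `cause = "none"` exactly for censored subjects.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_cohort_csv <- function(path) {
  df <- hi_read_csv(path, "cohort")
  check_columns(df, c("subject_id", "hi", "followup_days", "event", "cause"),
                sprintf("cohort file %s", basename(path)))
  if (any(!df$event %in% c(0, 1))) {
    abort_validation("`event` must be 0 or 1")
  }
  if (any(df$followup_days <= 0 | !is.finite(df$followup_days))) {
    abort_validation("`followup_days` must be positive and finite")
  }
  if (any(df$event == 0 & df$cause != "none") ||
      any(df$event == 1 & df$cause == "none")) {
    abort_validation("`cause` must be \"none\" exactly for censored subjects (event = 0)")
  }
  tibble::as_tibble(df)
}

#' Read reference ranges (and optional cut-offs) from a config JSON
#'
#' Schema:
#' `{"sampen": {"min": ..., "max": ...}, "nbp": {...}, "ugs": {...},
#'   "cutoffs": {"low_medium": 0.45, "medium_high": 0.65}}`
#' (the `cutoffs` block is optional).
#'
#' @param path JSON path.
#' @return A list with elements `ranges` (an `hi_reference_ranges`) and
#'   `cutoffs` (an [risk_cutoffs()] or `NULL`).
#' @export
read_reference_json <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("reference config not found: %s", path))
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in HI_COMPONENTS) {
    if (is.null(cfg[[nm]]$min) || is.null(cfg[[nm]]$max)) {
      abort_validation(sprintf("reference config must give min and max for `%s`", nm))
    }
  }
  ranges <- reference_ranges(
    sampen = c(cfg$sampen$min, cfg$sampen$max),
    nbp = c(cfg$nbp$min, cfg$nbp$max),
    ugs = c(cfg$ugs$min, cfg$ugs$max)
  )
  cutoffs <- NULL
  if (!is.null(cfg$cutoffs)) {
    cutoffs <- risk_cutoffs(cfg$cutoffs$low_medium, cfg$cutoffs$medium_high)
  }
  list(ranges = ranges, cutoffs = cutoffs)
}

#' Write reference ranges (and cut-offs) to a config JSON
#'
#' @param ranges An `hi_reference_ranges`.
#' @param path Output path.
#' @param cutoffs Optional [risk_cutoffs()] to embed.
#' @return Invisibly, `path`.
#' @export
write_reference_json <- function(ranges, path, cutoffs = NULL) {
  stopifnot(inherits(ranges, "hi_reference_ranges"))
  obj <- stats::setNames(
    lapply(HI_COMPONENTS, function(nm) {
      row <- ranges[ranges$component == nm, ]
      list(min = row$min, max = row$max, worse = row$worse)
    }),
    HI_COMPONENTS
  )
  if (!is.null(cutoffs)) {
    obj$cutoffs <- list(low_medium = cutoffs$low_medium,
                        medium_high = cutoffs$medium_high)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
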