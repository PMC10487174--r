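#' Usual gait speed from walk records
#'
#' Usual gait speed (UGS) is the arithmetic mean of the steady-state speeds of
#' a subject's walks, in cm/s. Acceleration/deceleration exclusion is assumed
#' to have happened upstream on the instrumented walkway; this function takes
#' steady-state speeds as given.
#'
#' @param walk_speeds Numeric vector of positive, finite walk speeds (cm/s).
#' @return The mean speed. A single-walk record is accepted with a warning.
#' @examples
#' compute_ugs(c(130, 140))  # 135
#' @export
compute_ugs <- function(walk_speeds) {
  walk_speeds <- walk_speeds[!is.na(walk_speeds)]
  if (length(walk_speeds) == 0L) {
    abort_validation("no walk speeds provided")
  }
  if (any(!is.finite(walk_speeds) | walk_speeds <= 0)) {
    abort_validation("walk speeds must be finite and positive")
  }
  if (length(walk_speeds) == 1L) {
    warn_hi("single-walk record: usual gait speed based on one walk only")
  }
  mean(walk_speeds)
}

#' Usual gait speed for a cohort
#'
#' @param gait A data frame with columns `subject_id`, `walk1_cms` and
#'   optionally `walk2_cms` (second walk may be missing per subject).
#' @return A tibble `subject_id`, `ugs_cms`, `n_walks`, with invalid subjects
#'   excluded and itemised in the `excluded` attribute.
#' @export
compute_gait_speed <- function(gait) {
  check_columns(gait, c("subject_id", "walk1_cms"), "gait table")
  gait <- tibble::as_tibble(gait)
  if (!"walk2_cms" %in% names(gait)) gait$walk2_cms <- NA_real_
  rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(gait))) {
    speeds <- c(gait$walk1_cms[[i]], gait$walk2_cms[[i]])
    res <- tryCatch(
      withCallingHandlers(
        compute_ugs(speeds),
        hi_warning = function(w) invokeRestart("muffleWarning")
      ),
      hi_validation_error = function(e) {
        excluded[[length(excluded) + 1L]] <<- tibble::tibble(
          subject_id = gait$subject_id[[i]], reason = conditionMessage(e)
        )
        NULL
      }
    )
    if (!is.null(res)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = gait$subject_id[[i]],
        ugs_cms = res,
        n_walks = sum(!is.na(speeds))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  excl <- dplyr::bind_rows(excluded)
  if (nrow(excl) > 0L) {
    warn_hi(sprintf("excluded %d subject(s) with invalid gait data", nrow(excl)))
  }
  if (any(out$n_walks == 1L)) {
    warn_hi(sprintf("%d subject(s) have a single-walk gait record",
                    sum(out$n_walks == 1L)))
  }
  attr(out, "excluded") <- excl
  out
}
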