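# SART protocol constants: 23 cycles of the digits 1..9, NO-GO on the digit 3.
SART_N_CYCLES <- 23L
SART_CYCLE_LEN <- 9L
SART_N_TRIALS <- SART_N_CYCLES * SART_CYCLE_LEN  # 207
SART_NOGO_DIGIT <- 3L

#' Parse and validate a SART trial log
#'
#' The Sustained Attention to Response Task presents the digits 1 to 9 in 23
#' consecutive cycles (207 trials); participants respond to every digit except
#' 3 (the NO-GO digit). A reaction time of 0 ms encodes "no key press".
#'
#' Validation enforces: digits in 1..9, non-negative finite reaction times, and
#' a complete session of 207 trials (unless `allow_partial = TRUE`, which keeps
#' only complete 9-trial cycles and records how many were scored). A digit
#' sequence that deviates from the repeating 1..9 pattern is flagged with a
#' warning but still scored -- each row's recorded digit is authoritative.
#'
#' @param rows A data frame with columns `trial`, `digit`, `rt_ms`, ordered by
#'   trial index.
#' @param allow_partial Accept sessions with fewer than 207 trials, scoring
#'   only complete cycles. Default `FALSE`.
#' @return A tibble of class `sart_session` with columns `trial`, `digit`,
#'   `rt_ms`, `cycle`.
#' @export
parse_sart_log <- function(rows, allow_partial = FALSE) {
  check_columns(rows, c("trial", "digit", "rt_ms"), "SART trial log")
  rows <- tibble::as_tibble(rows)[c("trial", "digit", "rt_ms")]
  if (is.unsorted(rows$trial, strictly = TRUE)) {
    abort_validation("SART rows must be strictly ordered by trial index")
  }
  bad_digit <- which(is.na(rows$digit) | rows$digit %% 1 != 0 |
                       rows$digit < 1 | rows$digit > 9)
  if (length(bad_digit) > 0L) {
    abort_validation(sprintf(
      "digit outside 1..9 at row %d (trial %s)",
      bad_digit[[1L]], format(rows$trial[bad_digit[[1L]]])
    ))
  }
  bad_rt <- which(is.na(rows$rt_ms) | !is.finite(rows$rt_ms) | rows$rt_ms < 0)
  if (length(bad_rt) > 0L) {
    abort_validation(sprintf(
      "invalid reaction time at row %d (trial %s): must be a finite number >= 0",
      bad_rt[[1L]], format(rows$trial[bad_rt[[1L]]])
    ))
  }

  n <- nrow(rows)
  if (n != SART_N_TRIALS) {
    if (!allow_partial) {
      abort_validation(sprintf(
        "incomplete session: %d trials, expected %d", n, SART_N_TRIALS
      ))
    }
    n_cycles <- n %/% SART_CYCLE_LEN
    if (n_cycles == 0L) {
      abort_validation("partial session has no complete 9-trial cycle")
    }
    rows <- rows[seq_len(n_cycles * SART_CYCLE_LEN), , drop = FALSE]
  }

  expected <- rep.int(1:9, nrow(rows) / SART_CYCLE_LEN)
  pattern_ok <- all(rows$digit == expected)
  if (!pattern_ok) {
    warn_hi("digit sequence deviates from the repeating 1..9 pattern; scoring uses the recorded digits")
  }

  rows$cycle <- rep(seq_len(nrow(rows) / SART_CYCLE_LEN), each = SART_CYCLE_LEN)
  structure(rows, class = c("sart_session", class(rows)),
            pattern_ok = pattern_ok)
}

#' Per-cycle mistake counts
#'
#' A mistake is either a commission error (key press on the NO-GO digit 3) or
#' an omission error (no key press on a GO digit). Each 9-trial cycle can
#' therefore accumulate up to 9 mistakes.
#'
#' @param session A `sart_session` from [parse_sart_log()].
#' @param min_rt_ms Optional anticipation filter: responses faster than this
#'   (but > 0) are treated as no response. Default 0 (off).
#' @return A tibble with columns `cycle`, `commissions`, `omissions`,
#'   `mistakes`.
#' @export
cycle_mistakes <- function(session, min_rt_ms = 0) {
  stopifnot(inherits(session, "sart_session"))
  responded <- session$rt_ms >= max(min_rt_ms, .Machine$double.eps) &
    session$rt_ms > 0
  nogo <- session$digit == SART_NOGO_DIGIT
  df <- tibble::tibble(
    cycle = session$cycle,
    commission = nogo & responded,
    omission = !nogo & !responded
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, cycle),
    commissions = sum(commission),
    omissions = sum(omission),
    .groups = "drop"
  )
  out$mistakes <- out$commissions + out$omissions
  out
}

#' Number of bad performances (NBP)
#'
#' A cycle is a "bad performance" when it contains at least 2 mistakes out of
#' its 9 possible actions; the NBP is the count of such cycles, ranging 0 to
#' 23 for a complete session.
#'
#' @inheritParams cycle_mistakes
#' @return An integer count of bad-performance cycles.
#' @export
count_nbp <- function(session, min_rt_ms = 0) {
  sum(cycle_mistakes(session, min_rt_ms = min_rt_ms)$mistakes >= 2L)
}

#' Summarise a SART session
#'
#' @inheritParams cycle_mistakes
#' @return A one-row tibble: `n_trials`, `n_cycles`, `commission_errors`,
#'   `omission_errors`, `nbp`, `mean_go_rt_ms` (mean reaction time over
#'   responded GO trials; `NA` when every GO trial was omitted).
#' @export
summarize_session <- function(session, min_rt_ms = 0) {
  stopifnot(inherits(session, "sart_session"))
  cm <- cycle_mistakes(session, min_rt_ms = min_rt_ms)
  responded <- session$rt_ms > 0 & session$rt_ms >= max(min_rt_ms, 0)
  go_rt <- session$rt_ms[session$digit != SART_NOGO_DIGIT & responded]
  tibble::tibble(
    n_trials = nrow(session),
    n_cycles = nrow(cm),
    commission_errors = sum(cm$commissions),
    omission_errors = sum(cm$omissions),
    nbp = sum(cm$mistakes >= 2L),
    mean_go_rt_ms = if (length(go_rt) > 0L) mean(go_rt) else NA_real_
  )
}

#' Score SART sessions for a cohort
#'
#' Parses and summarises one session per subject from a long trial table.
#' Subjects whose log fails validation are excluded and itemised in the
#' `excluded` attribute (subject id + reason) with a warning, never silently
#' dropped.
#'
#' @param trials A data frame with columns `subject_id`, `trial`, `digit`,
#'   `rt_ms`.
#' @inheritParams parse_sart_log
#' @inheritParams cycle_mistakes
#' @return A tibble with one row per valid subject (columns of
#'   [summarize_session()] plus `subject_id`), with attribute `excluded`.
#' @export
score_sart <- function(trials, allow_partial = FALSE, min_rt_ms = 0) {
  check_columns(trials, c("subject_id", "trial", "digit", "rt_ms"), "SART table")
  ids <- unique(trials$subject_id)
  pieces <- split(tibble::as_tibble(trials), trials$subject_id)[as.character(ids)]
  excluded <- list()
  rows <- list()
  for (id in names(pieces)) {
    res <- tryCatch(
      {
        s <- withCallingHandlers(
          parse_sart_log(pieces[[id]], allow_partial = allow_partial),
          hi_warning = function(w) invokeRestart("muffleWarning")
        )
        dplyr::bind_cols(tibble::tibble(subject_id = pieces[[id]]$subject_id[[1L]]),
                         summarize_session(s, min_rt_ms = min_rt_ms))
      },
      hi_validation_error = function(e) {
        excluded[[id]] <<- tibble::tibble(
          subject_id = pieces[[id]]$subject_id[[1L]],
          reason = conditionMessage(e)
        )
        NULL
      }
    )
    if (!is.null(res)) rows[[id]] <- res
  }
  out <- dplyr::bind_rows(rows)
  excl <- dplyr::bind_rows(excluded)
  if (nrow(excl) > 0L) {
    warn_hi(sprintf("excluded %d subject(s) with invalid SART data: %s",
                    nrow(excl), paste(excl$subject_id, collapse = ", ")))
  }
  attr(out, "excluded") <- excl
  out
}
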