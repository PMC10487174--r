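#' Template match fractions for sample entropy
#'
#' Counts, for each length-`m` template vector of the series, the fraction of
#' other templates lying within a Chebyshev distance of `r` times the series
#' standard deviation, and likewise for templates of length `m + 1`. These are
#' the \eqn{B^m(r)} and \eqn{A^m(r)} averages from which sample entropy is
#' formed: both averages run over template start positions \eqn{i = 1..N-m},
#' self-matches are excluded, and each per-template count is divided by
#' \eqn{N - m - 1}.
#'
#' A constant series is legal: the tolerance is then zero and exact ties still
#' match (the similarity test uses a closed ball), so all match fractions are 1.
#'
#' @param x Numeric vector, the series (e.g. beat-to-beat systolic blood
#'   pressure in mmHg). Must be finite and of length at least `m + 2`.
#' @param m Embedding dimension (template length), a positive integer.
#'   Default 1.
#' @param r Similarity criterion as a multiple of the series SD. Default 0.4.
#' @param sd_type Whether the tolerance uses the population SD (divisor `N`,
#'   the default) or the sample SD (divisor `N - 1`) of the analysed window.
#'
#' @return A list with elements `b_mean`, `a_mean` (average match fractions for
#'   template lengths `m` and `m + 1`) and `n` (series length).
#' @seealso [sample_entropy()]
#' @export
match_counts <- function(x, m = 1, r = 0.4,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_validation("`x` must be a numeric vector with no missing or non-finite values")
  }
  check_number(m, "m", lower = 1)
  if (m != round(m)) abort_validation("`m` must be a whole number")
  m <- as.integer(m)
  check_number(r, "r", lower = .Machine$double.eps)
  n <- length(x)
  if (n < m + 2L) {
    abort_validation(sprintf(
      "series too short for sample entropy: length %d < m + 2 = %d", n, m + 2L
    ))
  }

  sdx <- if (sd_type == "population") {
    sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd(x)
  }
  tol <- r * sdx

  nt <- n - m                       # template start positions i = 1..N-m
  idx <- seq_len(nt)
  d <- abs(outer(x, x, "-"))
  # Chebyshev distance between templates is the running max of the pointwise
  # distance matrix along the diagonal offset.
  dm <- d[idx, idx, drop = FALSE]
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      dm <- pmax(dm, d[idx + k, idx + k, drop = FALSE])
    }
  }
  dm1 <- pmax(dm, d[idx + m, idx + m, drop = FALSE])

  denom <- n - m - 1L
  b_i <- (rowSums(dm <= tol) - 1) / denom   # -1 removes the self-match
  a_i <- (rowSums(dm1 <= tol) - 1) / denom
  list(b_mean = mean(b_i), a_mean = mean(a_i), n = n)
}

#' Sample entropy of a series
#'
#' Sample entropy (SampEn) is \eqn{-\ln(A^m(r) / B^m(r))}: the negative log of
#' the conditional probability that two sequences matching for `m` points
#' within tolerance `r` times the series SD also match at the next point.
#' Higher values indicate a more irregular, less predictable signal; a constant
#' or perfectly self-similar series scores 0.
#'
#' When no template pairs match at length `m` or `m + 1` the statistic is
#' undefined; this is signalled by returning `NA` with a warning, so the caller
#' decides whether to exclude the subject.
#'
#' @inheritParams match_counts
#' @return A single non-negative number, or `NA` when the entropy is undefined
#'   (zero matches at either template length).
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(60), m = 1, r = 0.4)
#' sample_entropy(rep(120, 60))  # constant series -> 0
#' @export
sample_entropy <- function(x, m = 1, r = 0.4,
                           sd_type = c("population", "sample")) {
  mc <- match_counts(x, m = m, r = r, sd_type = sd_type)
  if (mc$b_mean == 0 || mc$a_mean == 0) {
    warn_hi(sprintf(
      "sample entropy undefined: no template matches at length %s",
      if (mc$b_mean == 0) "m" else "m + 1"
    ))
    return(NA_real_)
  }
  -log(mc$a_mean / mc$b_mean)
}

#' Restrict a beat series to the final resting-state window
#'
#' Keeps the suffix of a beat-to-beat recording spanning the final
#' `duration_s` seconds, the resting-state window over which entropy is
#' computed. When beat times are present (column `time_s`) the window is
#' selected by timestamp with a closed lower boundary, so a series whose total
#' span is exactly `duration_s` is returned unchanged. Without timestamps the
#' window is the last `round(duration_s * beat_rate)` beats.
#'
#' @param bp A data frame with column `sbp_mmhg` and optionally `time_s`
#'   (strictly increasing beat onset times in seconds).
#' @param duration_s Window length in seconds. Default 60 (final minute).
#' @param beat_rate Expected beat rate in beats per second, used only when
#'   `time_s` is absent. Default 1.
#' @return The input rows falling in the window, as a tibble, order preserved.
#' @export
select_resting_window <- function(bp, duration_s = 60, beat_rate = 1) {
  check_columns(bp, "sbp_mmhg", "beat series")
  check_number(duration_s, "duration_s", lower = .Machine$double.eps)
  check_number(beat_rate, "beat_rate", lower = .Machine$double.eps)
  validate_beat_series(bp)
  bp <- tibble::as_tibble(bp)

  if ("time_s" %in% names(bp) && !all(is.na(bp$time_s))) {
    span <- max(bp$time_s) - min(bp$time_s)
    if (span < duration_s) {
      abort_validation(sprintf(
        "insufficient data: series spans %.1f s, need %.1f s", span, duration_s
      ))
    }
    bp[bp$time_s >= max(bp$time_s) - duration_s, , drop = FALSE]
  } else {
    k <- round(duration_s * beat_rate)
    if (nrow(bp) < k) {
      abort_validation(sprintf(
        "insufficient data: %d beats, need %d (%.0f s at %.2f beats/s)",
        nrow(bp), k, duration_s, beat_rate
      ))
    }
    bp[seq.int(nrow(bp) - k + 1L, nrow(bp)), , drop = FALSE]
  }
}

validate_beat_series <- function(bp) {
  if (nrow(bp) == 0L) abort_validation("beat series is empty")
  v <- bp$sbp_mmhg
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
    abort_validation("all sBP values must be finite and positive")
  }
  if ("time_s" %in% names(bp) && !all(is.na(bp$time_s))) {
    t <- bp$time_s
    if (anyNA(t) || any(diff(t) <= 0)) {
      abort_validation("beat times must be complete and strictly increasing")
    }
  }
  invisible(bp)
}

#' Per-subject sample entropy of resting-state blood pressure
#'
#' Applies resting-window selection followed by [sample_entropy()] to each
#' subject of a long beat-to-beat table. Subjects whose series is too short
#' for the window, or whose entropy is undefined (zero template matches), are
#' returned with `sampen = NA` and `defined = FALSE` together with a warning;
#' they are never dropped silently.
#'
#' @param bp A data frame with columns `subject_id`, `sbp_mmhg` and optionally
#'   `time_s`, ordered by beat within subject.
#' @inheritParams match_counts
#' @inheritParams select_resting_window
#' @return A tibble with one row per subject: `subject_id`, `n_beats` (beats in
#'   the analysed window), `sampen`, `defined`.
#' @export
compute_sampen <- function(bp, m = 1, r = 0.4, duration_s = 60, beat_rate = 1,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  check_columns(bp, c("subject_id", "sbp_mmhg"), "beat-to-beat table")
  pieces <- split(tibble::as_tibble(bp), bp$subject_id)
  out <- purrr::map(pieces, function(df) {
    res <- tryCatch(
      {
        win <- select_resting_window(df, duration_s = duration_s,
                                     beat_rate = beat_rate)
        se <- withCallingHandlers(
          sample_entropy(win$sbp_mmhg, m = m, r = r, sd_type = sd_type),
          hi_warning = function(w) invokeRestart("muffleWarning")
        )
        list(n = nrow(win), sampen = se)
      },
      hi_validation_error = function(e) list(n = nrow(df), sampen = NA_real_,
                                             reason = conditionMessage(e))
    )
    tibble::tibble(
      subject_id = df$subject_id[[1L]],
      n_beats = res$n,
      sampen = res$sampen,
      defined = is.finite(res$sampen)
    )
  })
  out <- dplyr::bind_rows(out)
  n_bad <- sum(!out$defined)
  if (n_bad > 0L) {
    warn_hi(sprintf(
      "sample entropy undefined or not computable for %d subject(s): %s",
      n_bad, paste(out$subject_id[!out$defined], collapse = ", ")
    ))
  }
  out[order(match(out$subject_id, unique(bp$subject_id))), , drop = FALSE]
}
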