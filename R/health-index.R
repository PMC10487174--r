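# Component naming and risk directions for the 3-item index. Higher entropy
# and more bad performances are worse; faster gait is better, so gait is
# inverted during normalisation.
HI_COMPONENTS <- c("sampen", "nbp", "ugs")
HI_WORSE <- c(sampen = "higher", nbp = "higher", ugs = "lower")

#' Reference ranges for index normalisation
#'
#' Constructs the per-component minimum/maximum used to min-max scale the three
#' components onto \[0, 1\]. The worse-direction of each component is fixed:
#' higher for sample entropy and the bad-performance count, lower for gait
#' speed.
#'
#' @param sampen,nbp,ugs Length-2 numeric vectors `c(min, max)` with
#'   `min < max`.
#' @return A tibble of class `hi_reference_ranges` with columns `component`,
#'   `min`, `max`, `worse`.
#' @export
reference_ranges <- function(sampen, nbp, ugs) {
  vals <- list(sampen = sampen, nbp = nbp, ugs = ugs)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 2L || anyNA(v) || any(!is.finite(v)) || v[[1L]] >= v[[2L]]) {
      abort_validation(sprintf(
        "reference range for `%s` must be c(min, max) with min < max", nm
      ))
    }
  }
  out <- tibble::tibble(
    component = HI_COMPONENTS,
    min = unname(vapply(vals, `[[`, numeric(1), 1L)),
    max = unname(vapply(vals, `[[`, numeric(1), 2L)),
    worse = unname(HI_WORSE[HI_COMPONENTS])
  )
  structure(out, class = c("hi_reference_ranges", class(out)))
}

#' Fit reference ranges from a cohort
#'
#' Takes the observed minimum and maximum of each component over a reference
#' cohort, the full-range normalisation used to place each component on
#' \[0, 1\].
#'
#' @param components A data frame with numeric columns `sampen`, `nbp`, `ugs`
#'   (one row per subject); rows with any missing component are ignored.
#' @return An `hi_reference_ranges` object.
#' @export
fit_reference_ranges <- function(components) {
  check_columns(components, HI_COMPONENTS, "component table")
  cc <- stats::complete.cases(components[HI_COMPONENTS])
  components <- components[cc, , drop = FALSE]
  if (nrow(components) < 2L) {
    abort_validation("need at least 2 subjects with complete components to fit ranges")
  }
  rng <- lapply(HI_COMPONENTS, function(nm) {
    v <- range(components[[nm]])
    if (v[[1L]] == v[[2L]]) {
      abort_validation(sprintf(
        "component `%s` has zero variance in the reference cohort; range undefined", nm
      ))
    }
    v
  })
  names(rng) <- HI_COMPONENTS
  reference_ranges(sampen = rng$sampen, nbp = rng$nbp, ugs = rng$ugs)
}

#' Min-max normalise a component value
#'
#' Scales `value` to \[0, 1\] against a reference range so that 0 is the best
#' and 1 the worst observed extreme: `(value - min) / (max - min)`, inverted
#' (`1 - scaled`) when lower values are worse (gait speed). Values outside the
#' reference range are clamped to \[0, 1\] with a warning.
#'
#' @param value Numeric vector of raw component values.
#' @param min,max Reference range endpoints, `min < max`.
#' @param worse `"higher"` or `"lower"`: the direction of worse health.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_component <- function(value, min, max, worse = c("higher", "lower")) {
  worse <- match.arg(worse)
  if (anyNA(value) || any(!is.finite(value))) {
    abort_validation("component values must be finite for normalisation")
  }
  if (!is.finite(min) || !is.finite(max) || min >= max) {
    abort_validation("invalid reference range: need min < max, both finite")
  }
  scaled <- (value - min) / (max - min)
  if (any(scaled < 0 | scaled > 1)) {
    warn_hi(sprintf(
      "%d value(s) outside the reference range were clamped to [0, 1]",
      sum(scaled < 0 | scaled > 1)
    ))
    scaled <- pmin(pmax(scaled, 0), 1)
  }
  if (worse == "lower") 1 - scaled else scaled
}

#' Risk-group cut-offs
#'
#' Holds the two boundaries that partition the index into Low-, Medium- and
#' High-Risk groups. Defaults are the data-driven values 0.45 and 0.65.
#'
#' @param low_medium,medium_high Boundaries with
#'   `0 < low_medium < medium_high < 1`.
#' @return A list of class `hi_risk_cutoffs`.
#' @export
risk_cutoffs <- function(low_medium = 0.45, medium_high = 0.65) {
  check_number(low_medium, "low_medium", lower = 1e-12, upper = 1 - 1e-12)
  check_number(medium_high, "medium_high", lower = 1e-12, upper = 1 - 1e-12)
  if (low_medium >= medium_high) {
    abort_validation("`low_medium` must be strictly below `medium_high`")
  }
  structure(list(low_medium = low_medium, medium_high = medium_high),
            class = "hi_risk_cutoffs")
}

#' @export
print.hi_risk_cutoffs <- function(x, ...) {
  cat(sprintf("Risk-group cut-offs: Low < %.3f <= Medium < %.3f <= High\n",
              x$low_medium, x$medium_high))
  invisible(x)
}

#' Assign risk groups from index values
#'
#' Half-open convention: a value equal to a cut-off belongs to the worse group,
#' so `hi = low_medium` is Medium-Risk and `hi = medium_high` is High-Risk.
#'
#' @param hi Numeric vector of index values in \[0, 1\].
#' @param cutoffs An [risk_cutoffs()] object.
#' @return An ordered factor with levels `Low`, `Medium`, `High`.
#' @export
assign_risk_group <- function(hi, cutoffs = risk_cutoffs()) {
  stopifnot(inherits(cutoffs, "hi_risk_cutoffs"))
  if (anyNA(hi) || any(hi < 0 | hi > 1)) {
    abort_validation("index values must lie in [0, 1] for risk-group assignment")
  }
  cut(hi, breaks = c(-Inf, cutoffs$low_medium, cutoffs$medium_high, Inf),
      labels = c("Low", "Medium", "High"), right = FALSE, ordered_result = TRUE)
}

#' Compute the 3-item health index for a cohort
#'
#' Normalises each subject's sample entropy, bad-performance count and usual
#' gait speed against the reference ranges and averages the three normalised
#' components with equal weight, giving an index on \[0, 1\] where higher is
#' worse. Subjects with any missing component are excluded and itemised in the
#' `excluded` attribute with a warning (a composite cannot be formed from a
#' partial profile).
#'
#' @param components A data frame with columns `subject_id`, `sampen`, `nbp`,
#'   `ugs`.
#' @param ranges An `hi_reference_ranges` object (or `NULL` to fit from
#'   `components` itself).
#' @param cutoffs An [risk_cutoffs()] object used for group assignment.
#' @return A tibble with the raw components, `sampen_norm`, `nbp_norm`,
#'   `ugs_norm`, `hi`, and `risk_group`, one row per complete subject.
#' @examples
#' rng <- reference_ranges(sampen = c(0.2, 1.2), nbp = c(0, 23), ugs = c(60, 180))
#' compute_health_index(
#'   data.frame(subject_id = "s1", sampen = 0.7, nbp = 4, ugs = 130), rng
#' )
#' @export
compute_health_index <- function(components, ranges = NULL,
                                 cutoffs = risk_cutoffs()) {
  check_columns(components, c("subject_id", HI_COMPONENTS), "component table")
  components <- tibble::as_tibble(components)
  if (is.null(ranges)) ranges <- fit_reference_ranges(components)
  stopifnot(inherits(ranges, "hi_reference_ranges"))

  complete <- stats::complete.cases(components[HI_COMPONENTS])
  excl <- tibble::tibble(
    subject_id = components$subject_id[!complete],
    reason = "incomplete subject: missing index component"
  )
  if (nrow(excl) > 0L) {
    warn_hi(sprintf("excluded %d subject(s) with incomplete components: %s",
                    nrow(excl), paste(excl$subject_id, collapse = ", ")))
  }
  out <- components[complete, , drop = FALSE]

  norm <- lapply(HI_COMPONENTS, function(nm) {
    row <- ranges[ranges$component == nm, ]
    normalize_component(out[[nm]], row$min, row$max, row$worse)
  })
  names(norm) <- paste0(HI_COMPONENTS, "_norm")
  out <- dplyr::bind_cols(out, tibble::as_tibble(norm))
  out$hi <- (out$sampen_norm + out$nbp_norm + out$ugs_norm) / 3
  out$risk_group <- assign_risk_group(out$hi, cutoffs)
  attr(out, "excluded") <- excl
  out
}

#' Compute the index for a single subject
#'
#' Scalar convenience around [compute_health_index()]; errors (rather than
#' excluding) when a component is missing.
#'
#' @param sampen,nbp,ugs Raw component values for one subject.
#' @inheritParams compute_health_index
#' @return A one-row tibble as returned by [compute_health_index()].
#' @export
compute_hi <- function(sampen, nbp, ugs, ranges, cutoffs = risk_cutoffs()) {
  if (anyNA(c(sampen, nbp, ugs))) {
    abort_validation("incomplete subject: all three components are required")
  }
  compute_health_index(
    tibble::tibble(subject_id = "subject", sampen = sampen, nbp = nbp, ugs = ugs),
    ranges = ranges, cutoffs = cutoffs
  )
}
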