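#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted Cox exposure model
#'
#' One row per non-reference exposure level (and, for adjusted models,
#' per covariate term), in hazard-ratio scale.
#'
#' @param x An `hi_coxfit` from [fit_cox()].
#' @param exposure_only Keep only the exposure terms. Default `TRUE`.
#' @param ... Unused.
#' @return A tibble `term`, `level`, `hr`, `ci_low`, `ci_high`, `p`.
#' @method tidy hi_coxfit
#' @export
tidy.hi_coxfit <- function(x, exposure_only = TRUE, ...) {
  tab <- x$table
  if (exposure_only) tab <- tab[tab$exposure_term, , drop = FALSE]
  tab[c("term", "level", "hr", "ci_low", "ci_high", "p")]
}

#' One-row model summary for a fitted Cox exposure model
#'
#' @param x An `hi_coxfit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `endpoint`, `adjusted`,
#'   `concordance`, `logLik`.
#' @method glance hi_coxfit
#' @export
glance.hi_coxfit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    endpoint = x$endpoint,
    adjusted = x$adjusted,
    concordance = unname(summary(x$fit)$concordance[["C"]]),
    logLik = as.numeric(stats::logLik(x$fit))
  )
}

#' Tidy a cut-off scan
#'
#' @param x An `hi_cutoff_scan` from [scan_cutoffs()].
#' @param ... Unused.
#' @return The scan as a plain tibble.
#' @method tidy hi_cutoff_scan
#' @export
tidy.hi_cutoff_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy derived risk-group cut-offs
#'
#' @param x An `hi_derived_cutoffs` from [derive_risk_groups()].
#' @param ... Unused.
#' @return A tibble `boundary`, `cutoff`.
#' @method tidy hi_derived_cutoffs
#' @export
tidy.hi_derived_cutoffs <- function(x, ...) {
  tibble::tibble(
    boundary = c("low_medium", "medium_high"),
    cutoff = c(x$low_medium, x$medium_high)
  )
}
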