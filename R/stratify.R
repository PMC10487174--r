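HI_ENDPOINTS <- c("all_cause", "cardio_respiratory")
HI_CARDIORESP_CAUSES <- c("cardiovascular", "respiratory")

# Covariates of the fully adjusted mortality models.
HI_ADJUST_COVARIATES <- c("age", "sex", "education", "bmi_cat", "antihtn",
                          "diabetes", "n_cvd", "smoking", "alcohol")

#' Default candidate grid for the cut-off search
#'
#' Candidate index cut-offs from 0.2 to 0.65 in steps of 0.025 (19 values).
#' @return A numeric vector.
#' @export
cutoff_grid <- function() seq(0.2, 0.65, by = 0.025)

# Recode follow-up/event columns for an endpoint. For the cause-specific
# cardio-respiratory endpoint, deaths from other causes are censored at the
# death time (cause-specific hazard convention).
endpoint_outcome <- function(cohort, endpoint = HI_ENDPOINTS) {
  endpoint <- match.arg(endpoint)
  check_columns(cohort, c("followup_days", "event"), "cohort table")
  if (any(cohort$followup_days <= 0, na.rm = TRUE)) {
    abort_validation("`followup_days` must be positive")
  }
  event <- as.integer(cohort$event)
  if (endpoint == "cardio_respiratory") {
    check_columns(cohort, "cause", "cohort table (cause-specific endpoint)")
    event <- as.integer(event == 1L & cohort$cause %in% HI_CARDIORESP_CAUSES)
  }
  tibble::tibble(time = cohort$followup_days, status = event)
}

#' Grid search of univariate Cox models over candidate cut-offs
#'
#' For each candidate cut-off `c`, fits a univariate Cox proportional-hazards
#' model on the binary indicator `hi >= c` and records the hazard ratio of the
#' upper group, its Wald p-value, and group sizes. Candidates that leave one
#' side empty, have no events on one side, or fail to converge are flagged
#' `usable = FALSE` but kept in the table.
#'
#' @param cohort A data frame with columns `hi`, `followup_days`, `event` and,
#'   for the cause-specific endpoint, `cause`.
#' @param grid Numeric vector of candidate cut-offs. Default [cutoff_grid()].
#' @param endpoint `"all_cause"` (default) or `"cardio_respiratory"`.
#' @return A tibble of class `hi_cutoff_scan` with columns `cutoff`, `n_above`,
#'   `events_above`, `events_below`, `hr`, `p`, `usable`.
#' @export
scan_cutoffs <- function(cohort, grid = cutoff_grid(),
                         endpoint = c("all_cause", "cardio_respiratory")) {
  endpoint <- match.arg(endpoint)
  check_columns(cohort, "hi", "cohort table")
  out <- endpoint_outcome(cohort, endpoint)
  if (sum(out$status) == 0L) {
    abort_fit(sprintf("no events for endpoint `%s`; cannot scan cut-offs", endpoint))
  }
  if (length(grid) == 0L || anyNA(grid)) {
    abort_validation("`grid` must be a non-empty numeric vector")
  }

  rows <- purrr::map(sort(unique(grid)), function(cc) {
    above <- cohort$hi >= cc
    n_above <- sum(above)
    ev_above <- sum(out$status[above])
    ev_below <- sum(out$status[!above])
    base <- tibble::tibble(
      cutoff = cc, n_above = n_above,
      events_above = ev_above, events_below = ev_below,
      hr = NA_real_, p = NA_real_, usable = FALSE
    )
    if (n_above == 0L || n_above == nrow(cohort) ||
        ev_above == 0L || ev_below == 0L) {
      return(base)
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(out$time, out$status) ~ above, ties = "efron"
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(stats::coef(fit)) ||
        abs(stats::coef(fit)) > 15) {  # monotone-likelihood guard
      return(base)
    }
    sm <- summary(fit)$coefficients
    base$hr <- unname(exp(stats::coef(fit)))
    base$p <- unname(sm[1L, "Pr(>|z|)"])
    base$usable <- TRUE
    base
  })
  scan <- dplyr::bind_rows(rows)
  structure(scan, class = c("hi_cutoff_scan", class(scan)), endpoint = endpoint)
}

#' Select the optimal cut-off from a scan
#'
#' The search aims for the split that maximises the hazard ratio while
#' minimising the p-value. Those two criteria need not agree, so the default
#' rule takes the usable candidate with the smallest p-value, breaking ties by
#' larger hazard ratio and then by smaller cut-off; `rule = "max_hr"` instead
#' ranks by hazard ratio first.
#'
#' @param scan An `hi_cutoff_scan` from [scan_cutoffs()].
#' @param rule `"min_p"` (default) or `"max_hr"`.
#' @return The selected cut-off (a single number).
#' @export
select_cutoff <- function(scan, rule = c("min_p", "max_hr")) {
  rule <- match.arg(rule)
  stopifnot(inherits(scan, "hi_cutoff_scan"))
  ok <- scan[scan$usable, , drop = FALSE]
  if (nrow(ok) == 0L) {
    abort_fit("no usable candidate cut-off in the scan")
  }
  ord <- if (rule == "min_p") {
    order(ok$p, -ok$hr, ok$cutoff)
  } else {
    order(-ok$hr, ok$p, ok$cutoff)
  }
  ok$cutoff[ord[[1L]]]
}

#' Derive Low/Medium/High risk-group cut-offs from survival data
#'
#' Two-stage data-driven search. Stage one scans the full cohort for the
#' cut-off separating Low-Risk subjects from the rest. Stage two repeats the
#' scan restricted to subjects at or above the first cut-off, over grid
#' candidates strictly above it, separating Medium- from High-Risk. With
#' `second_stage = "full"` the second scan instead uses the full cohort over
#' candidates above the first cut-off.
#'
#' @inheritParams scan_cutoffs
#' @inheritParams select_cutoff
#' @param second_stage `"restricted"` (default) or `"full"`.
#' @param min_subjects,min_events Minimum size of the second-stage subset;
#'   below either, the second cut-off is reported as unavailable (`NA`).
#' @return A list of class `hi_derived_cutoffs`: `low_medium`, `medium_high`
#'   (possibly `NA`), `cutoffs` (an [risk_cutoffs()] when both stages
#'   succeeded), and the two scan tables.
#' @export
derive_risk_groups <- function(cohort, grid = cutoff_grid(),
                               endpoint = c("all_cause", "cardio_respiratory"),
                               rule = c("min_p", "max_hr"),
                               second_stage = c("restricted", "full"),
                               min_subjects = 20, min_events = 5) {
  endpoint <- match.arg(endpoint)
  rule <- match.arg(rule)
  second_stage <- match.arg(second_stage)

  scan1 <- scan_cutoffs(cohort, grid = grid, endpoint = endpoint)
  c1 <- select_cutoff(scan1, rule = rule)

  grid2 <- grid[grid > c1]
  subset2 <- if (second_stage == "restricted") {
    cohort[cohort$hi >= c1, , drop = FALSE]
  } else {
    cohort
  }
  out2 <- endpoint_outcome(subset2, endpoint)
  scan2 <- NULL
  c2 <- NA_real_
  if (length(grid2) == 0L) {
    warn_hi("no grid candidates above the first cut-off; second cut-off unavailable")
  } else if (nrow(subset2) < min_subjects || sum(out2$status) < min_events) {
    warn_hi(sprintf(
      "second-stage subset too small (%d subjects, %d events); second cut-off unavailable",
      nrow(subset2), sum(out2$status)
    ))
  } else {
    scan2 <- tryCatch(
      scan_cutoffs(subset2, grid = grid2, endpoint = endpoint),
      hi_fit_error = function(e) NULL
    )
    if (!is.null(scan2)) {
      c2 <- tryCatch(select_cutoff(scan2, rule = rule),
                     hi_fit_error = function(e) NA_real_)
    }
    if (is.na(c2)) warn_hi("second-stage scan had no usable candidate; second cut-off unavailable")
  }

  structure(
    list(
      low_medium = c1,
      medium_high = c2,
      cutoffs = if (!is.na(c2)) risk_cutoffs(c1, c2) else NULL,
      scan_low_medium = scan1,
      scan_medium_high = scan2
    ),
    class = "hi_derived_cutoffs"
  )
}

#' @export
print.hi_derived_cutoffs <- function(x, ...) {
  cat(sprintf("Derived cut-offs: low/medium = %.3f, medium/high = %s\n",
              x$low_medium,
              if (is.na(x$medium_high)) "unavailable" else sprintf("%.3f", x$medium_high)))
  invisible(x)
}

#' Cox proportional-hazards model for a categorical exposure
#'
#' Fits a Cox model of the chosen mortality endpoint on a categorical exposure
#' (risk group, frailty class, ...), optionally adjusted for the standard
#' covariate set (age, sex, education, BMI category, antihypertensive use,
#' diabetes, number of cardiovascular conditions, smoking, alcohol). Subjects
#' without an event are right-censored at the end of their follow-up; the
#' cause-specific endpoint censors other-cause deaths at the death time. Ties
#' are handled with the Efron approximation.
#'
#' @inheritParams scan_cutoffs
#' @param exposure Name of the exposure column (string). Its first factor
#'   level is the reference.
#' @param adjusted Include the covariate set. Default `FALSE`.
#' @param covariates Covariate column names used when `adjusted = TRUE`.
#' @return An object of class `hi_coxfit`; see [tidy.hi_coxfit()] for the
#'   per-level hazard-ratio table.
#' @export
fit_cox <- function(cohort, exposure, adjusted = FALSE,
                    endpoint = c("all_cause", "cardio_respiratory"),
                    covariates = HI_ADJUST_COVARIATES) {
  endpoint <- match.arg(endpoint)
  check_columns(cohort, exposure, "cohort table")
  if (adjusted) check_columns(cohort, covariates, "cohort table (adjusted model)")
  out <- endpoint_outcome(cohort, endpoint)
  if (sum(out$status) == 0L) abort_fit("no events for the requested endpoint")

  dat <- tibble::as_tibble(cohort)
  dat$.time <- out$time
  dat$.status <- out$status
  if (!is.factor(dat[[exposure]])) dat[[exposure]] <- factor(dat[[exposure]])
  # treatment contrasts against the first level, even for ordered factors
  dat[[exposure]] <- factor(as.character(dat[[exposure]]),
                            levels = levels(dat[[exposure]]))
  dat[[exposure]] <- droplevels(dat[[exposure]])
  if (nlevels(dat[[exposure]]) < 2L) {
    abort_fit(sprintf("exposure `%s` has fewer than 2 observed levels", exposure))
  }

  rhs <- paste(c(sprintf("`%s`", exposure),
                 if (adjusted) sprintf("`%s`", covariates)), collapse = " + ")
  form <- stats::as.formula(paste("survival::Surv(.time, .status) ~", rhs))
  fit <- tryCatch(
    survival::coxph(form, data = dat, ties = "efron"),
    error = function(e) abort_fit(sprintf("Cox model failed to fit: %s",
                                          conditionMessage(e)))
  )
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15)) {
    abort_fit("Cox model did not converge (possible separation: a level with no events or all events)")
  }

  sm <- summary(fit)
  coefs <- sm$coefficients
  ci <- sm$conf.int
  terms <- rownames(coefs)
  exp_terms <- startsWith(terms, sprintf("`%s`", exposure)) |
    startsWith(terms, exposure)
  levels_ <- sub(sprintf("^`?%s`?", exposure), "", terms)
  table <- tibble::tibble(
    term = terms,
    level = levels_,
    exposure_term = exp_terms,
    hr = unname(ci[, "exp(coef)"]),
    ci_low = unname(ci[, 3L]),
    ci_high = unname(ci[, 4L]),
    p = unname(coefs[, "Pr(>|z|)"])
  )
  structure(
    list(fit = fit, table = table, exposure = exposure,
         reference = levels(dat[[exposure]])[[1L]],
         endpoint = endpoint, adjusted = adjusted,
         n = fit$n, n_events = fit$nevent),
    class = "hi_coxfit"
  )
}

#' @export
print.hi_coxfit <- function(x, ...) {
  cat(sprintf("Cox model (%s, %s): %d subjects, %d events; reference %s = %s\n",
              x$endpoint, if (x$adjusted) "adjusted" else "unadjusted",
              x$n, x$n_events, x$exposure, x$reference))
  print(x$table[x$table$exposure_term,
                c("level", "hr", "ci_low", "ci_high", "p")])
  invisible(x)
}

#' ROC area under the curve for a mortality score
#'
#' Nonparametric AUC of a score for the binary died-by-end-of-follow-up label
#' of the chosen endpoint; equals the Mann-Whitney concordance probability
#' (tied score pairs count one half).
#'
#' @inheritParams scan_cutoffs
#' @param score Name of the score column (e.g. `"hi"` or a competitor index).
#' @return A single number in \[0, 1\].
#' @export
roc_auc <- function(cohort, score = "hi",
                    endpoint = c("all_cause", "cardio_respiratory")) {
  endpoint <- match.arg(endpoint)
  check_columns(cohort, score, "cohort table")
  out <- endpoint_outcome(cohort, endpoint)
  x <- cohort[[score]]
  if (!is.numeric(x)) x <- as.numeric(x)
  if (length(unique(out$status)) < 2L) {
    abort_validation("both outcome classes (died / survived) are required for ROC analysis")
  }
  roc <- pROC::roc(response = out$status, predictor = x,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(roc))
}

#' ROC curve points for a mortality score
#'
#' @inheritParams roc_auc
#' @return A tibble of class `hi_roc` with columns `threshold`, `fpr`, `tpr`
#'   and attributes `auc`, `score`, `endpoint`.
#' @export
roc_curve <- function(cohort, score = "hi",
                      endpoint = c("all_cause", "cardio_respiratory")) {
  endpoint <- match.arg(endpoint)
  check_columns(cohort, score, "cohort table")
  out <- endpoint_outcome(cohort, endpoint)
  if (length(unique(out$status)) < 2L) {
    abort_validation("both outcome classes (died / survived) are required for ROC analysis")
  }
  roc <- pROC::roc(response = out$status, predictor = as.numeric(cohort[[score]]),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- tibble::tibble(
    threshold = roc$thresholds,
    fpr = 1 - roc$specificities,
    tpr = roc$sensitivities
  )
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  structure(pts, class = c("hi_roc", class(pts)),
            auc = as.numeric(pROC::auc(roc)), score = score, endpoint = endpoint)
}

#' BMI categories
#'
#' Body mass index (weight\[kg\] / height\[m\]^2) mapped to the WHO-style
#' half-open categories: underweight/normal (< 25), overweight (25 to < 30),
#' obese (30 to < 35), morbidly obese (>= 35).
#'
#' @param weight_kg,height_m Positive numeric vectors.
#' @return A factor with the four category levels.
#' @export
categorize_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg) | weight_kg <= 0) ||
      any(!is.finite(height_m) | height_m <= 0)) {
    abort_validation("weight and height must be finite and positive")
  }
  bmi_category(weight_kg / height_m^2)
}

#' @rdname categorize_bmi
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @export
bmi_category <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) {
    abort_validation("BMI must be finite and positive")
  }
  cut(bmi, breaks = c(-Inf, 25, 30, 35, Inf), right = FALSE,
      labels = c("underweight/normal", "overweight", "obese", "morbidly obese"))
}
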