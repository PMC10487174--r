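make_scan <- function(df) {
  if (!"usable" %in% names(df)) df$usable <- TRUE
  structure(tibble::as_tibble(df), class = c("hi_cutoff_scan", class(tibble::tibble())))
}

test_that("the default grid holds 19 candidates and all are evaluated", {
  expect_length(cutoff_grid(), 19)
  set.seed(61)
  cohort <- make_surv_cohort(500, lambda0 = 0.02, beta = 0)
  scan <- scan_cutoffs(cohort)
  expect_equal(nrow(scan), 19)
  expect_equal(scan$cutoff, cutoff_grid())
  expect_true(all(c("hr", "p", "n_above", "usable") %in% names(scan)))
})

test_that("hazard ratios centre on 1 when the outcome is independent of the index", {
  set.seed(62)
  cohort <- make_surv_cohort(1200, lambda0 = 0.02, beta = 0)
  scan <- scan_cutoffs(cohort)
  ok <- scan[scan$usable, ]
  expect_gt(nrow(ok), 10)
  expect_lt(abs(mean(log(ok$hr))), 0.3)
})

test_that("cut-off selection minimises p with hazard-ratio tie-breaks", {
  scan <- make_scan(tibble::tibble(
    cutoff = c(0.3, 0.4, 0.5), n_above = c(50, 40, 30),
    events_above = c(10, 9, 8), events_below = c(5, 6, 7),
    hr = c(2.8, 3.1, 2.0), p = c(0.01, 0.01, 0.2)
  ))
  expect_equal(select_cutoff(scan), 0.4)   # equal p, larger HR wins
  scan$p <- c(0.05, 0.2, 0.001)
  expect_equal(select_cutoff(scan), 0.5)   # smallest p wins
  scan$hr <- c(3, 3, 3); scan$p <- c(0.01, 0.01, 0.01)
  expect_equal(select_cutoff(scan), 0.3)   # full tie: smaller cut-off
  scan$usable <- FALSE
  expect_error(select_cutoff(scan), class = "hi_fit_error")
})

test_that("unusable candidates are flagged, not dropped", {
  set.seed(63)
  cohort <- make_surv_cohort(300, lambda0 = 0.02, beta = 0,
                             hi = runif(300, 0, 0.5))
  scan <- scan_cutoffs(cohort)
  expect_equal(nrow(scan), 19)
  high <- scan[scan$cutoff > 0.5, ]
  expect_true(all(!high$usable))
  expect_true(all(is.na(high$hr)))
})

test_that("a planted hazard step is recovered within one grid step", {
  set.seed(64)
  hits <- 0L
  for (k in 1:10) {
    cohort <- make_surv_cohort(2000, lambda0 = 0.01, beta = 0,
                               step_at = 0.45, step_log_hr = log(3))
    sel <- select_cutoff(scan_cutoffs(cohort))
    if (abs(sel - 0.45) <= 0.025 + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("two-stage derivation returns ordered cut-offs and composes with scans", {
  set.seed(65)
  # skewed index distribution: most subjects low-risk, a thin high tail
  hi <- c(runif(3380, 0.05, 0.449), runif(588, 0.45, 0.649),
          runif(32, 0.65, 0.85))
  cohort <- make_surv_cohort(4000, lambda0 = 0.006, beta = 0, hi = hi,
                             step_at = c(0.45, 0.65),
                             step_log_hr = c(log(3.3), log(1.8)))
  derived <- suppressWarnings(derive_risk_groups(cohort))
  expect_s3_class(derived, "hi_derived_cutoffs")
  expect_false(is.na(derived$medium_high))
  expect_lt(derived$low_medium, derived$medium_high)
  expect_s3_class(derived$cutoffs, "hi_risk_cutoffs")

  # the second-stage scan equals a fresh scan of the restricted cohort
  c1 <- derived$low_medium
  manual <- scan_cutoffs(cohort[cohort$hi >= c1, ],
                         grid = cutoff_grid()[cutoff_grid() > c1])
  expect_equal(tidy(derived$scan_medium_high), tidy(manual))
})

test_that("degenerate cohorts fail both stages with informative errors", {
  set.seed(66)
  low <- make_surv_cohort(200, lambda0 = 0.05, beta = 0, hi = runif(200, 0, 0.15))
  expect_error(derive_risk_groups(low), class = "hi_fit_error")
  no_events <- make_surv_cohort(50, lambda0 = 1e-9, beta = 0)
  expect_error(scan_cutoffs(no_events), "no events", class = "hi_fit_error")
})

test_that("a small second-stage subset reports the second cut-off as unavailable", {
  set.seed(67)
  hi <- c(runif(400, 0, 0.6), runif(8, 0.62, 0.9))
  cohort <- make_surv_cohort(408, lambda0 = 0.02, beta = 0,
                             step_at = 0.6, step_log_hr = log(4), hi = hi)
  derived <- suppressWarnings(
    derive_risk_groups(cohort, min_subjects = 20, min_events = 5)
  )
  if (derived$low_medium >= 0.6) {
    expect_true(is.na(derived$medium_high))
    expect_null(derived$cutoffs)
  } else {
    succeed("first-stage cut-off fell below the sparse tail; subset not small")
  }
})

test_that("Cox fits recover a planted group effect and report Wald inference", {
  set.seed(68)
  hi <- runif(2000)
  cohort <- make_surv_cohort(2000, lambda0 = 0.01, beta = 0, hi = hi,
                             step_at = 0.5, step_log_hr = log(3))
  cohort$group <- factor(ifelse(hi >= 0.5, "high", "low"),
                         levels = c("low", "high"))
  fit <- fit_cox(cohort, "group")
  tab <- tidy(fit)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$ci_high, 3 * 0.99)
  expect_lt(tab$ci_low, 3 * 1.01)
  expect_lt(abs(log(tab$hr) - log(3)), 0.35)
  g <- glance(fit)
  expect_equal(g$n, 2000)
  expect_equal(g$n_events, sum(cohort$event))
})

test_that("a null exposure gives hazard ratios near 1", {
  set.seed(69)
  cohort <- make_surv_cohort(1500, lambda0 = 0.02, beta = 0)
  cohort$group <- factor(sample(c("a", "b"), 1500, replace = TRUE))
  tab <- tidy(fit_cox(cohort, "group"))
  expect_lt(abs(log(tab$hr)), 0.35)
})

test_that("adjustment moves the estimate toward the truth under planted confounding", {
  set.seed(70)
  n <- 3000
  group <- rbinom(n, 1, 0.5)
  confounder <- group * 1.0 + rnorm(n)      # associated with exposure
  true_log_hr <- log(2)
  lp <- true_log_hr * group + 0.8 * confounder
  t_event <- rexp(n, rate = 0.02 * exp(lp))
  cohort <- tibble::tibble(
    subject_id = as.character(seq_len(n)),
    hi = runif(n),
    followup_days = pmin(t_event, 12) * 365.25,
    event = as.integer(t_event <= 12),
    cause = ifelse(t_event <= 12, "other", "none"),
    group = factor(ifelse(group == 1, "exposed", "ref"),
                   levels = c("ref", "exposed")),
    confounder = confounder
  )
  unadj <- tidy(fit_cox(cohort, "group"))
  adj <- tidy(fit_cox(cohort, "group", adjusted = TRUE,
                      covariates = "confounder"))
  expect_lt(abs(log(adj$hr) - true_log_hr), abs(log(unadj$hr) - true_log_hr))
})

test_that("separation and single-level exposures raise fitting errors", {
  set.seed(71)
  cohort <- make_surv_cohort(100, lambda0 = 0.02, beta = 0)
  cohort$group <- factor(rep("only", 100))
  expect_error(fit_cox(cohort, "group"), class = "hi_fit_error")
})

test_that("cause-specific endpoints censor competing deaths and conserve subjects", {
  set.seed(72)
  cohort <- make_surv_cohort(800, lambda0 = 0.05, beta = 1)
  cohort$group <- factor(ifelse(cohort$hi >= 0.5, "high", "low"),
                         levels = c("low", "high"))
  for (ep in c("all_cause", "cardio_respiratory")) {
    fit <- fit_cox(cohort, "group", endpoint = ep)
    expected_events <- if (ep == "all_cause") {
      sum(cohort$event)
    } else {
      sum(cohort$event == 1 & cohort$cause %in% c("cardiovascular", "respiratory"))
    }
    expect_equal(glance(fit)$n_events, expected_events)
    expect_equal(glance(fit)$n, nrow(cohort))  # censored + events
  }
  expect_lt(glance(fit_cox(cohort, "group", endpoint = "cardio_respiratory"))$n_events,
            sum(cohort$event))
})

test_that("AUC equals the all-pairs concordance probability, ties counting half", {
  set.seed(73)
  for (k in 1:8) {
    n <- 120
    cohort <- make_surv_cohort(n, lambda0 = 0.05, beta = 2,
                               hi = round(runif(n), 1))  # forces score ties
    label <- cohort$event
    if (length(unique(label)) < 2) next
    expect_equal(roc_auc(cohort, "hi"), auc_oracle(cohort$hi, label),
                 tolerance = 1e-12)
  }
})

test_that("AUC endpoints: chance for an uninformative score, 1 for the label itself", {
  set.seed(74)
  cohort <- make_surv_cohort(800, lambda0 = 0.03, beta = 0)
  cohort$noise <- rnorm(800)
  expect_lt(abs(roc_auc(cohort, "noise") - 0.5), 0.07)
  cohort$oracle_score <- cohort$event
  expect_equal(roc_auc(cohort, "oracle_score"), 1)
  one_class <- cohort[cohort$event == 0, ]
  expect_error(roc_auc(one_class, "hi"), class = "hi_validation_error")
})

test_that("ROC curve points are monotone and carry the AUC", {
  set.seed(75)
  cohort <- make_surv_cohort(300, lambda0 = 0.04, beta = 2)
  rc <- roc_curve(cohort, "hi")
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(attr(rc, "auc"), roc_auc(cohort, "hi"), tolerance = 1e-12)
})

test_that("BMI categories follow the half-open boundaries", {
  expect_equal(as.character(categorize_bmi(70, 1.75)), "underweight/normal")
  expect_equal(as.character(bmi_category(25)), "overweight")
  expect_equal(as.character(bmi_category(29.99)), "overweight")
  expect_equal(as.character(bmi_category(30)), "obese")
  expect_equal(as.character(bmi_category(35)), "morbidly obese")
  expect_error(categorize_bmi(-70, 1.75), class = "hi_validation_error")
})
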