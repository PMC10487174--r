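#' Parameters of the synthetic cohort generator
#'
#' Bundles all knobs of the generator: the beat-to-beat blood pressure model
#' (baseline + sinusoidal slow oscillation + AR(1) noise; the noise SD is the
#' irregularity knob driving sample entropy), the SART behaviour model
#' (per-trial omission and commission probabilities, GO reaction-time
#' distribution), the gait model, a shared latent frailty factor correlating
#' the three domains, and the survival model (exponential proportional
#' hazards with log-hazard linear in the true index, optional planted step
#' terms, administrative censoring at the follow-up horizon).
#'
#' Defaults emulate a community-dwelling older cohort: gait speeds around
#' 136 cm/s, ages 61 +/- 8 years truncated at 50, about 54% female, and a
#' baseline hazard giving roughly 10% all-cause mortality over the 12-year
#' horizon, with cardiovascular/respiratory deaths increasingly likely at
#' high index values.
#'
#' @param n_subjects Number of subjects.
#' @param bp,sart,gait,survival Named lists overriding individual model
#'   parameters; see the function body for the complete set and defaults.
#' @param frailty_cor Correlation of each domain's subject-level severity with
#'   the shared latent frailty factor, in \[0, 1\).
#' @return A list of class `hi_sim_params`.
#' @export
cohort_sim_params <- function(n_subjects = 100, bp = list(), sart = list(),
                              gait = list(), survival = list(),
                              frailty_cor = 0.6) {
  check_number(n_subjects, "n_subjects", lower = 1)
  check_number(frailty_cor, "frailty_cor", lower = 0, upper = 1 - 1e-9)
  defaults <- list(
    bp = list(
      n_beats = 300L,          # ~5 min of supine rest at 1 beat/s
      beat_interval_s = 1.0,
      baseline_mmhg = 120, baseline_sd = 15,
      osc_amp_mmhg = 6, osc_period_s = 40,
      noise_sd_mmhg = 1.5,     # median irregularity
      noise_sd_sdlog = 0.5,    # between-subject spread of the noise SD
      ar = 0.5                 # lag-1 autocorrelation of the noise
    ),
    sart = list(
      p_omit = 0.03, omit_sdlog = 1.2,   # logit-normal between-subject spread
      p_commit = 0.45, commit_sdlog = 0.8,
      rt_mean_ms = 390, rt_sd_ms = 80, rt_min_ms = 150
    ),
    gait = list(mean_cms = 136, sd_cms = 20, walk_sd_cms = 5, min_cms = 40),
    survival = list(
      lambda0 = 0.008,         # baseline hazard per year at hi = hi_center
      beta = 3,                # log-hazard slope per unit of index
      hi_center = 0.35,
      step_at = numeric(0), step_log_hr = numeric(0),
      age_beta = 0.05,         # per year above 60; confounds age with outcome
      horizon_years = 12,
      loss_rate = 0,           # random loss to follow-up per year (off)
      cause_intercept = -1, cause_beta = 4  # logit P(cardio-resp | death)
    )
  )
  p <- defaults
  p$bp[names(bp)] <- bp
  p$sart[names(sart)] <- sart
  p$gait[names(gait)] <- gait
  p$survival[names(survival)] <- survival
  p$n_subjects <- as.integer(n_subjects)
  p$frailty_cor <- frailty_cor
  for (prob in c("p_omit", "p_commit")) {
    check_number(p$sart[[prob]], prob, lower = 0, upper = 1)
  }
  structure(p, class = "hi_sim_params")
}

#' Simulate one subject's beat-to-beat blood pressure series
#'
#' Beat values are baseline + a sinusoidal slow oscillation + stationary AR(1)
#' Gaussian noise with marginal SD `noise_sd`. A larger noise-to-oscillation
#' ratio yields stochastically larger sample entropy; `noise_sd = 0` gives a
#' smooth periodic series with entropy near zero.
#'
#' @param n_beats Number of beats (>= 60).
#' @param baseline Mean sBP in mmHg.
#' @param osc_amp,osc_period Amplitude (mmHg) and period (s) of the slow
#'   oscillation.
#' @param noise_sd Marginal SD of the AR(1) noise (mmHg).
#' @param ar Lag-1 autocorrelation of the noise in \[0, 1).
#' @param beat_interval_s Seconds between beats.
#' @return A tibble `beat`, `time_s`, `sbp_mmhg`.
#' @export
simulate_bp_series <- function(n_beats = 300, baseline = 120, osc_amp = 6,
                               osc_period = 40, noise_sd = 1.5, ar = 0.5,
                               beat_interval_s = 1.0) {
  check_number(n_beats, "n_beats", lower = 60)
  n_beats <- as.integer(n_beats)
  t <- (seq_len(n_beats) - 1L) * beat_interval_s
  osc <- osc_amp * sin(2 * pi * t / osc_period)
  noise <- if (noise_sd > 0) {
    innov <- stats::rnorm(n_beats, sd = noise_sd * sqrt(1 - ar^2))
    as.numeric(stats::filter(innov, ar, method = "recursive"))
  } else {
    rep(0, n_beats)
  }
  tibble::tibble(
    beat = seq_len(n_beats),
    time_s = t,
    sbp_mmhg = baseline + osc + noise
  )
}

#' Simulate one SART session
#'
#' 207 trials (23 cycles of the digits 1..9). Each GO trial is omitted with
#' probability `p_omit`, otherwise its reaction time is drawn from a normal
#' distribution truncated below at `rt_min_ms`; each NO-GO trial (digit 3)
#' receives a response with probability `p_commit`.
#'
#' @param p_omit,p_commit Per-trial lapse probabilities in \[0, 1\].
#' @param rt_mean_ms,rt_sd_ms,rt_min_ms GO reaction-time distribution (ms).
#' @return A tibble `trial`, `digit`, `rt_ms` with 207 rows.
#' @export
simulate_sart_session <- function(p_omit = 0.03, p_commit = 0.45,
                                  rt_mean_ms = 390, rt_sd_ms = 80,
                                  rt_min_ms = 150) {
  check_number(p_omit, "p_omit", lower = 0, upper = 1)
  check_number(p_commit, "p_commit", lower = 0, upper = 1)
  digit <- rep.int(1:9, SART_N_CYCLES)
  n <- length(digit)
  rt <- numeric(n)
  go <- digit != SART_NOGO_DIGIT
  respond <- logical(n)
  respond[go] <- stats::runif(sum(go)) >= p_omit
  respond[!go] <- stats::runif(sum(!go)) < p_commit
  rt[respond] <- pmax(stats::rnorm(sum(respond), rt_mean_ms, rt_sd_ms), rt_min_ms)
  tibble::tibble(trial = seq_len(n), digit = digit, rt_ms = rt)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with rate
#' `lambda0 * exp(beta * (hi - hi_center) + planted steps + extra)` per year.
#' Times beyond the follow-up horizon are administratively censored at the
#' horizon; optional random loss to follow-up censors earlier. Among deaths,
#' the cause is cardio-respiratory with probability
#' `plogis(cause_intercept + cause_beta * (hi - hi_center))` -- so
#' cardiovascular and respiratory deaths are enriched at high index values --
#' split 115:30 between cardiovascular and respiratory; the remainder split
#' 190:81 between cancer and other.
#'
#' @param hi Numeric vector of true index values, one per subject.
#' @param lambda0 Baseline hazard per year.
#' @param beta Log-hazard slope on `hi`.
#' @param hi_center Index value at which the hazard equals `lambda0`.
#' @param step_at,step_log_hr Optional planted thresholds and the log
#'   hazard-ratio added when `hi >= step_at` (equal lengths).
#' @param extra_log_hazard Optional per-subject additive log-hazard (e.g.
#'   covariate effects).
#' @param horizon_years Administrative censoring horizon.
#' @param loss_rate Exponential loss-to-follow-up rate per year (0 = off).
#' @param cause_intercept,cause_beta Logistic model of P(cardio-respiratory
#'   cause | death) in `hi`.
#' @return A tibble `followup_days`, `event`, `cause`.
#' @export
simulate_survival <- function(hi, lambda0 = 0.008, beta = 3, hi_center = 0.35,
                              step_at = numeric(0), step_log_hr = numeric(0),
                              extra_log_hazard = 0, horizon_years = 12,
                              loss_rate = 0, cause_intercept = -1,
                              cause_beta = 4) {
  stopifnot(length(step_at) == length(step_log_hr))
  if (any(!is.finite(c(lambda0, beta, step_log_hr, extra_log_hazard)))) {
    abort_validation("hazard parameters must be finite")
  }
  n <- length(hi)
  log_h <- log(lambda0) + beta * (hi - hi_center) + rep_len(extra_log_hazard, n)
  for (k in seq_along(step_at)) {
    log_h <- log_h + step_log_hr[[k]] * (hi >= step_at[[k]])
  }
  t_event <- stats::rexp(n, rate = exp(log_h))
  t_cens <- if (loss_rate > 0) {
    pmin(stats::rexp(n, rate = loss_rate), horizon_years)
  } else {
    rep(horizon_years, n)
  }
  event <- as.integer(t_event <= t_cens)
  time_years <- pmin(t_event, t_cens)

  cause <- rep("none", n)
  if (any(event == 1L)) {
    idx <- which(event == 1L)
    p_cr <- stats::plogis(cause_intercept + cause_beta * (hi[idx] - hi_center))
    is_cr <- stats::runif(length(idx)) < p_cr
    # cardio:respiratory 115:30 and cancer:other 190:81 among deaths
    cause[idx[is_cr]] <- sample(c("cardiovascular", "respiratory"),
                                sum(is_cr), replace = TRUE,
                                prob = c(115, 30))
    cause[idx[!is_cr]] <- sample(c("cancer", "other"),
                                 sum(!is_cr), replace = TRUE,
                                 prob = c(190, 81))
  }
  tibble::tibble(
    followup_days = pmax(time_years, 1e-6) * 365.25,
    event = event,
    cause = cause
  )
}

# Latent value correlated with the shared frailty factor u.
latent_mix <- function(u, rho) rho * u + sqrt(1 - rho^2) * stats::rnorm(length(u))

#' Simulate a complete synthetic cohort
#'
#' Generates, per subject: a beat-to-beat sBP series, a SART session, two gait
#' walks, and covariates -- all coupled through a shared latent frailty factor
#' so the three index components correlate realistically -- then scores the
#' components with the package's own pipeline, fits reference ranges on the
#' cohort, computes the true index, and draws survival outcomes from a
#' proportional-hazards model driven by that index (plus an age effect).
#'
#' @param params An [cohort_sim_params()] object.
#' @param seed Integer seed; identical `params` + `seed` give identical output.
#' @return A list of class `hi_sim_cohort` with tibbles `bp` (long,
#'   per-beat), `sart` (long, per-trial), `gait`, `cohort` (components, index,
#'   risk group, covariates, survival outcome), the fitted `ranges`, and the
#'   `params`/`seed` used.
#' @export
simulate_cohort <- function(params = cohort_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "hi_sim_params"))
  set.seed(seed)
  n <- params$n_subjects
  rho <- params$frailty_cor
  ids <- sprintf("S%04d", seq_len(n))
  u <- stats::rnorm(n)  # shared latent frailty, higher = worse

  # --- components -----------------------------------------------------------
  pb <- params$bp
  noise_sd <- pb$noise_sd_mmhg * exp(pb$noise_sd_sdlog * latent_mix(u, rho))
  baseline <- stats::rnorm(n, pb$baseline_mmhg, pb$baseline_sd)
  bp <- purrr::map2(seq_len(n), ids, function(i, id) {
    df <- simulate_bp_series(
      n_beats = pb$n_beats, baseline = baseline[[i]],
      osc_amp = pb$osc_amp_mmhg, osc_period = pb$osc_period_s,
      noise_sd = noise_sd[[i]], ar = pb$ar,
      beat_interval_s = pb$beat_interval_s
    )
    df$subject_id <- id
    df[c("subject_id", "beat", "time_s", "sbp_mmhg")]
  })
  bp <- dplyr::bind_rows(bp)

  ps <- params$sart
  p_omit <- stats::plogis(stats::qlogis(max(ps$p_omit, 1e-6)) +
                            ps$omit_sdlog * latent_mix(u, rho))
  p_commit <- stats::plogis(stats::qlogis(min(max(ps$p_commit, 1e-6), 1 - 1e-6)) +
                              ps$commit_sdlog * latent_mix(u, rho))
  # degenerate probabilities are exact, not jittered
  if (ps$p_omit == 0) p_omit <- rep(0, n)
  if (ps$p_omit == 1) p_omit <- rep(1, n)
  if (ps$p_commit == 0) p_commit <- rep(0, n)
  if (ps$p_commit == 1) p_commit <- rep(1, n)
  sart <- purrr::map2(seq_len(n), ids, function(i, id) {
    df <- simulate_sart_session(
      p_omit = p_omit[[i]], p_commit = p_commit[[i]],
      rt_mean_ms = ps$rt_mean_ms, rt_sd_ms = ps$rt_sd_ms,
      rt_min_ms = ps$rt_min_ms
    )
    df$subject_id <- id
    df[c("subject_id", "trial", "digit", "rt_ms")]
  })
  sart <- dplyr::bind_rows(sart)

  pg <- params$gait
  gait_mean <- pg$mean_cms - pg$sd_cms * latent_mix(u, rho)
  gait <- tibble::tibble(
    subject_id = ids,
    walk1_cms = pmax(gait_mean + stats::rnorm(n, 0, pg$walk_sd_cms), pg$min_cms),
    walk2_cms = pmax(gait_mean + stats::rnorm(n, 0, pg$walk_sd_cms), pg$min_cms)
  )

  # --- score with the package's own pipeline --------------------------------
  comp <- suppressWarnings(dplyr::full_join(
    dplyr::full_join(
      compute_sampen(bp)[c("subject_id", "sampen")],
      score_sart(sart)[c("subject_id", "nbp")],
      by = "subject_id"
    ),
    compute_gait_speed(gait)[c("subject_id", "ugs_cms")],
    by = "subject_id"
  ))
  names(comp)[names(comp) == "ugs_cms"] <- "ugs"
  ranges <- fit_reference_ranges(comp)
  hi_tab <- suppressWarnings(compute_health_index(comp, ranges = ranges))

  # --- covariates -----------------------------------------------------------
  age <- pmax(round(61.6 + 8.2 * latent_mix(u, 0.4)), 50)
  bmi <- stats::rnorm(n, 28, 4.5)
  cov <- tibble::tibble(
    subject_id = ids,
    age = age,
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.54, 0.46)),
    education = sample(c("primary", "secondary", "third_level"), n,
                       replace = TRUE, prob = c(0.21, 0.42, 0.37)),
    bmi_cat = bmi_category(pmax(bmi, 15)),
    antihtn = stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.33) + 0.3 * u)),
    diabetes = stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.06) + 0.3 * u)),
    n_cvd = pmin(stats::rpois(n, 0.2 * exp(0.3 * u)), 2L),
    smoking = sample(c("never", "past", "current"), n, replace = TRUE,
                     prob = c(0.46, 0.39, 0.15)),
    alcohol = sample(c("cage_lt2", "cage_ge2", "no_response"), n,
                     replace = TRUE, prob = c(0.78, 0.13, 0.09))
  )

  # --- survival driven by the true index ------------------------------------
  cohort <- dplyr::inner_join(hi_tab, cov, by = "subject_id")
  pv <- params$survival
  surv <- simulate_survival(
    hi = cohort$hi, lambda0 = pv$lambda0, beta = pv$beta,
    hi_center = pv$hi_center, step_at = pv$step_at,
    step_log_hr = pv$step_log_hr,
    extra_log_hazard = pv$age_beta * (cohort$age - 60),
    horizon_years = pv$horizon_years, loss_rate = pv$loss_rate,
    cause_intercept = pv$cause_intercept, cause_beta = pv$cause_beta
  )
  cohort <- dplyr::bind_cols(cohort, surv)

  structure(
    list(bp = bp, sart = sart, gait = gait, cohort = cohort,
         ranges = ranges, params = params, seed = as.integer(seed)),
    class = "hi_sim_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject blood pressure and SART CSVs, a gait CSV, and the cohort
#' survival/covariate CSV in the schemas the reader functions expect, plus a
#' manifest JSON recording the parameters, seed, file list and content hashes.
#'
#' @inheritParams simulate_cohort
#' @param dir Output directory. Existing generated files there cause an error
#'   unless `overwrite = TRUE`.
#' @param overwrite Replace existing files. Default `FALSE`.
#' @return Invisibly, the manifest list.
#' @export
generate_cohort <- function(params = cohort_sim_params(), seed = 1L,
                            dir, overwrite = FALSE) {
  sim <- simulate_cohort(params, seed = seed)
  dir.create(file.path(dir, "bp"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sart"), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    abort_validation(sprintf("output collision: %s already exists", manifest_path))
  }

  files <- character(0)
  for (id in unique(sim$bp$subject_id)) {
    path <- file.path(dir, "bp", paste0(id, ".csv"))
    df <- sim$bp[sim$bp$subject_id == id, c("beat", "time_s", "sbp_mmhg")]
    readr::write_csv(df, path)
    files <- c(files, path)
  }
  for (id in unique(sim$sart$subject_id)) {
    path <- file.path(dir, "sart", paste0(id, ".csv"))
    df <- sim$sart[sim$sart$subject_id == id, c("trial", "digit", "rt_ms")]
    readr::write_csv(df, path)
    files <- c(files, path)
  }
  gait_path <- file.path(dir, "gait.csv")
  readr::write_csv(sim$gait, gait_path)
  cohort_path <- file.path(dir, "cohort.csv")
  readr::write_csv(sim$cohort, cohort_path)
  files <- c(files, gait_path, cohort_path)

  manifest <- list(
    package = "healthindex3",
    seed = sim$seed,
    n_subjects = params$n_subjects,
    params = unclass(params),
    files = as.list(stats::setNames(
      unname(tools::md5sum(files)), sub("^/+", "", sub(dir, "", files, fixed = TRUE))
    ))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
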