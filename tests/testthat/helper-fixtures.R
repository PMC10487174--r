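# Hand-built SART sessions and small cohorts used across test files.

sart_trials <- function(rt_go = 400, rt_nogo = 0, n_cycles = 23) {
  digit <- rep.int(1:9, n_cycles)
  rt <- ifelse(digit == 3, rt_nogo, rt_go)
  tibble::tibble(trial = seq_along(digit), digit = digit, rt_ms = rt)
}

perfect_session <- function() parse_sart_log(sart_trials())

nonresponsive_session <- function() {
  parse_sart_log(sart_trials(rt_go = 0, rt_nogo = 0))
}

# Survival-only cohort: index values plus outcome columns, no raw signals.
make_surv_cohort <- function(n, lambda0 = 0.02, beta = 0, hi = NULL,
                             step_at = numeric(0), step_log_hr = numeric(0),
                             horizon = 12) {
  if (is.null(hi)) hi <- runif(n)
  out <- simulate_survival(hi, lambda0 = lambda0, beta = beta, hi_center = 0,
                           step_at = step_at, step_log_hr = step_log_hr,
                           horizon_years = horizon)
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("P%04d", seq_len(n)),
                                  hi = hi), out)
}
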