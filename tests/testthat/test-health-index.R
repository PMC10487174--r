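ranges_demo <- reference_ranges(sampen = c(0.2, 1.2), nbp = c(0, 23),
                                ugs = c(60, 180))

test_that("fitted reference ranges are the observed component extremes", {
  comp <- tibble::tibble(
    subject_id = c("a", "b"),
    sampen = c(0.2, 0.8), nbp = c(1, 9), ugs = c(100, 150)
  )
  rng <- fit_reference_ranges(comp)
  expect_equal(rng$min[rng$component == "sampen"], 0.2)
  expect_equal(rng$max[rng$component == "sampen"], 0.8)
  expect_equal(rng$worse, c("higher", "higher", "lower"))

  # duplicating a subject changes nothing
  rng2 <- fit_reference_ranges(dplyr::bind_rows(comp, comp[1, ]))
  expect_equal(tibble::as_tibble(rng2), tibble::as_tibble(rng))
})

test_that("fitted ranges match an independent column-wise scan", {
  set.seed(51)
  comp <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:100),
    sampen = runif(100, 0.1, 1.5),
    nbp = sample(0:23, 100, replace = TRUE),
    ugs = runif(100, 60, 190)
  )
  rng <- fit_reference_ranges(comp)
  for (nm in c("sampen", "nbp", "ugs")) {
    lo <- Inf; hi <- -Inf
    for (v in comp[[nm]]) {  # deliberate scalar scan, no min()/max() call
      if (v < lo) lo <- v
      if (v > hi) hi <- v
    }
    expect_equal(rng$min[rng$component == nm], lo)
    expect_equal(rng$max[rng$component == nm], hi)
  }
})

test_that("degenerate reference cohorts are rejected", {
  one <- tibble::tibble(subject_id = "a", sampen = 0.5, nbp = 3, ugs = 120)
  expect_error(fit_reference_ranges(one), class = "hi_validation_error")
  flat <- tibble::tibble(subject_id = c("a", "b"), sampen = c(0.5, 0.5),
                         nbp = c(1, 5), ugs = c(100, 150))
  expect_error(fit_reference_ranges(flat), "zero variance",
               class = "hi_validation_error")
})

test_that("normalisation maps range endpoints to 0/1 with direction inversion", {
  expect_equal(normalize_component(0.2, 0.2, 1.2, "higher"), 0)
  expect_equal(normalize_component(1.2, 0.2, 1.2, "higher"), 1)
  # fastest walker is best, slowest is worst
  expect_equal(normalize_component(180, 60, 180, "lower"), 0)
  expect_equal(normalize_component(60, 60, 180, "lower"), 1)
  expect_equal(normalize_component(0.7, 0.2, 1.2, "higher"), 0.5)
})

test_that("out-of-range values clamp to [0, 1] with a warning", {
  expect_warning(v <- normalize_component(2.0, 0.2, 1.2, "higher"),
                 "clamped", class = "hi_warning")
  expect_equal(v, 1)
  expect_warning(v2 <- normalize_component(40, 60, 180, "lower"),
                 class = "hi_warning")
  expect_equal(v2, 1)
  expect_error(normalize_component(NaN, 0, 1, "higher"),
               class = "hi_validation_error")
})

test_that("the index is the equal-weight mean and hits 1/0 at the extremes", {
  worst <- compute_hi(sampen = 1.2, nbp = 23, ugs = 60, ranges = ranges_demo)
  expect_equal(worst$hi, 1)
  best <- compute_hi(sampen = 0.2, nbp = 0, ugs = 180, ranges = ranges_demo)
  expect_equal(best$hi, 0)

  # normalised components (0.2, 0.4, 0.6) -> mean 0.4
  mid <- compute_hi(sampen = 0.2 + 0.2 * 1.0, nbp = 0.4 * 23,
                    ugs = 180 - 0.6 * 120, ranges = ranges_demo)
  expect_equal(mid$sampen_norm, 0.2)
  expect_equal(mid$nbp_norm, 0.4)
  expect_equal(mid$ugs_norm, 0.6)
  expect_equal(mid$hi, 0.4)
})

test_that("missing components exclude the subject (scalar API errors)", {
  expect_error(compute_hi(NA, 3, 120, ranges_demo), "incomplete",
               class = "hi_validation_error")
  comp <- tibble::tibble(
    subject_id = c("a", "b"),
    sampen = c(0.5, NA), nbp = c(3, 4), ugs = c(120, 130)
  )
  expect_warning(res <- compute_health_index(comp, ranges = ranges_demo),
                 class = "hi_warning")
  expect_equal(res$subject_id, "a")
  expect_equal(attr(res, "excluded")$subject_id, "b")
})

test_that("worsening any single component never decreases the index", {
  set.seed(52)
  for (k in 1:25) {
    sampen <- runif(1, 0.2, 1.1)
    nbp <- sample(0:20, 1)
    ugs <- runif(1, 70, 175)
    base <- compute_hi(sampen, nbp, ugs, ranges_demo)$hi
    expect_gte(compute_hi(sampen + 0.1, nbp, ugs, ranges_demo)$hi, base)
    expect_gte(compute_hi(sampen, nbp + 2, ugs, ranges_demo)$hi, base)
    expect_gte(compute_hi(sampen, nbp, ugs - 8, ranges_demo)$hi, base)
  }
})

test_that("the index is invariant to affine rescaling of a component and its range", {
  set.seed(53)
  for (k in 1:10) {
    sampen <- runif(1, 0.25, 1.15)
    a <- runif(1, 0.5, 3)
    b <- runif(1, -1, 1)
    scaled <- reference_ranges(sampen = a * c(0.2, 1.2) + b, nbp = c(0, 23),
                               ugs = c(60, 180))
    expect_equal(
      compute_hi(a * sampen + b, 5, 120, scaled)$hi,
      compute_hi(sampen, 5, 120, ranges_demo)$hi,
      tolerance = 1e-12
    )
  }
})

test_that("risk groups partition [0, 1] with cut-offs in the worse group", {
  cuts <- risk_cutoffs()
  expect_equal(as.character(assign_risk_group(0.30, cuts)), "Low")
  expect_equal(as.character(assign_risk_group(0.50, cuts)), "Medium")
  expect_equal(as.character(assign_risk_group(0.45, cuts)), "Medium")
  expect_equal(as.character(assign_risk_group(0.65, cuts)), "High")

  hi <- seq(0, 1, by = 0.01)
  groups <- assign_risk_group(hi, cuts)
  expect_false(anyNA(groups))
  expect_equal(nlevels(groups), 3)
  expect_error(assign_risk_group(1.2, cuts), class = "hi_validation_error")
})

test_that("cut-off constructor enforces ordering within (0, 1)", {
  expect_error(risk_cutoffs(0.6, 0.4), class = "hi_validation_error")
  expect_error(risk_cutoffs(0, 0.5), class = "hi_validation_error")
  expect_error(risk_cutoffs(0.5, 1), class = "hi_validation_error")
})
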