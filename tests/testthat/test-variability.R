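test_that("window SD uses the population denominator and matches brute force", {
  expect_equal(window_sd(c(0.5, 0.5, 0.5)), 0)
  expect_equal(window_sd(c(0.4, 0.6)), 0.1)
  expect_true(is.na(window_sd(0.5)))

  set.seed(41)
  for (rep in 1:10) {
    v <- runif(sample(2:40, 1), 0.3, 1.2)
    expect_equal(window_sd(v), brute_window_sd(v), tolerance = 1e-12)
  }
})

test_that("window SD is scale-equivariant and shift-invariant", {
  set.seed(42)
  v <- runif(20, 0.4, 1)
  expect_equal(window_sd(3 * v), 3 * window_sd(v))
  expect_equal(window_sd(-2 * v), 2 * window_sd(v))
  expect_equal(window_sd(v + 10), window_sd(v))
})

test_that("label merge aligns windows, drops unevaluable and validates partitions", {
  m <- make_meta()
  sim <- simulate_trial(m, segment_plan(180, "locked"), seed = 43)
  cl <- suppressWarnings(classify_trial(sim$trial))
  isi <- inter_step_intervals(sim$trial$steps)
  isi_w <- partition_windows(truncate_series(isi), 20, 180)

  recs <- merge_labels(isi_w, cl)
  expect_equal(nrow(recs), 9)
  expect_equal(recs$window_index, 1:9)
  expect_equal(recs$window_rescaled, (1:9) / 10)
  expect_true(all(recs$sd_isi >= 0))
  expect_equal(recs$subject_id, rep("S01", 9))

  # an unevaluable label drops its window
  cl2 <- cl
  cl2$windows$final_label[5] <- "unevaluable"
  recs2 <- merge_labels(isi_w, cl2)
  expect_equal(nrow(recs2), 8)
  expect_false(5 %in% recs2$window_index)
  expect_equal(attr(recs2, "dropped"), 1)

  # partition mismatch is an error
  isi_w2 <- partition_windows(truncate_series(isi, 60), 30, 60)
  expect_error(merge_labels(isi_w2, cl), "do not match")
})

test_that("variability fit recovers known coefficients within 3 SE", {
  truth <- c("(Intercept)" = 2.9725, "Stimuli: music" = 0.2254,
             "Tempi: n12" = 0.16, "Tempi: p12" = -0.197,
             "Lock_lab: unlocked" = 0.0594,
             "Tempi: p12 * Lock_lab: unlocked" = 0.279)
  recs <- generate_variability_dataset(truth, n_subjects = 12, seed = 44)
  fit <- fit_variability_model(recs)
  co <- fit$coefficients
  expect_equal(nrow(co), 22)  # Table 2 layout: 1 + 6 + 1 + 1 + 1 + 6 + 6
  for (nm in names(truth)) {
    row <- co[co$Parameter == nm, ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$Estimate - truth[[nm]]), 3 * row$Std.error)
  }
  # terms simulated at zero stay near zero
  zero <- co[!co$Parameter %in% names(truth), ]
  expect_true(all(abs(zero$Estimate) < 4 * zero$Std.error))
  # variance components of the right order
  expect_equal(fit$ranef_sd, 0.15, tolerance = 0.12)
  expect_equal(fit$resid_sd, 0.2, tolerance = 0.03)
})

test_that("null model recovers a bare intercept", {
  recs <- generate_variability_dataset(c("(Intercept)" = 1.7),
                                       n_subjects = 10, seed = 45)
  fit <- fit_variability_model(recs)
  co <- fit$coefficients
  expect_equal(co$Estimate[co$Parameter == "(Intercept)"], 1.7,
               tolerance = 0.2)
  others <- co[co$Parameter != "(Intercept)", ]
  expect_true(all(abs(others$Estimate) < 3.5 * others$Std.error))
})

test_that("duplicating records leaves point estimates unchanged", {
  truth <- c("(Intercept)" = 2.9, "Stimuli: music" = 0.22)
  recs <- generate_variability_dataset(truth, n_subjects = 8, seed = 46)
  f1 <- fit_variability_model(recs)
  f2 <- fit_variability_model(rbind(recs, recs))
  # REML variance components shift slightly, so GLS point estimates are
  # stable rather than bit-identical
  expect_lt(max(abs(f2$coefficients$Estimate - f1$coefficients$Estimate)),
            1e-3)
  expect_true(all(f2$coefficients$Std.error <= f1$coefficients$Std.error))
})

test_that("rescaling all SDs shifts only the intercept, by log(c)", {
  truth <- c("(Intercept)" = 2.5, "Stimuli: music" = 0.2,
             "Tempi: n8" = 0.13)
  recs <- generate_variability_dataset(truth, n_subjects = 8, seed = 47)
  f1 <- fit_variability_model(recs)
  recs2 <- recs
  recs2$sd_isi <- recs2$sd_isi * 3
  f2 <- fit_variability_model(recs2)
  i1 <- f1$coefficients$Parameter == "(Intercept)"
  expect_equal(f2$coefficients$Estimate[i1],
               f1$coefficients$Estimate[i1] + log(3), tolerance = 1e-8)
  expect_equal(f2$coefficients$Estimate[!i1],
               f1$coefficients$Estimate[!i1], tolerance = 1e-8)
})

test_that("zero SDs are rejected with a actionable message", {
  recs <- generate_variability_dataset(n_subjects = 4, seed = 48)
  recs$sd_isi[3] <- 0
  expect_error(fit_variability_model(recs), "positive")
})

test_that("backward reduction keeps true interactions and drops absent ones", {
  truth <- c("(Intercept)" = 2.97,
             "Tempi: n12" = 0.16, "Tempi: p12" = -0.197,
             "Stimuli: music" = 0.2254, "Lock_lab: unlocked" = 0.06,
             "Tempi: n12 * Stimuli: music" = -0.19,
             "Tempi: p12 * Stimuli: music" = 0.15,
             "Tempi: p12 * Lock_lab: unlocked" = 0.279,
             "Tempi: n12 * Lock_lab: unlocked" = 0.2)
  recs <- generate_variability_dataset(truth, n_subjects = 14, seed = 49)
  red <- model_reduction(recs)
  expect_true(all(c("Tempi:Stimuli", "Tempi:Lock") %in% red$retained))
  expect_false("Stimuli:Lock" %in% red$retained)

  # with no interactions simulated, the final model is main-effects-only
  recs0 <- generate_variability_dataset(
    c("(Intercept)" = 2.9, "Stimuli: music" = 0.2), n_subjects = 12,
    seed = 50)
  red0 <- model_reduction(recs0)
  expect_length(red0$retained, 0)
  # main effects always survive
  expect_true(all(c("Tempi: n12", "Stimuli: music", "Lock_lab: unlocked",
                    "Window_lab_resc") %in% red0$coefficients$Parameter))
})
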