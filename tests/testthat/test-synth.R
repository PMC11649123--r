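test_that("beat streams are isochronous with the right count", {
  b <- generate_beats(60, 10)
  expect_equal(b$times, 0:9)

  b <- generate_beats(75, 180)
  expect_length(b$times, 225)  # floor(180 / 0.8)
  expect_equal(diff(b$times), rep(0.8, 224), tolerance = 1e-9)

  # +12% offset on baseline 75 spm is an 84 bpm stream
  m <- trial_meta("S01", "music", 12L, baseline_cadence = 75)
  bpm <- m$baseline_cadence * (1 + m$tempo_offset / 100)
  expect_equal(bpm, 84)
  expect_equal(diff(generate_beats(bpm, 10)$times)[1], 60 / 84,
               tolerance = 1e-9)
})

test_that("noiseless fully locked steps coincide with beats", {
  beats <- generate_beats(75, 60)
  plan <- segment_plan(60, "locked", offset_deg = 0, kappa = Inf)
  # kappa = Inf is not samplable; use a huge finite concentration
  plan$kappa <- 1e9
  steps <- generate_steps(beats, plan, timing_noise_sd = 0, seed = 51)
  rpa <- relative_phase_angles(steps, beats)
  expect_true(all(abs(rpa$rpa_deg) < 1))
})

test_that("drift segments advance the phase at the detuning rate", {
  beats <- generate_beats(75, 180)  # IBI 0.8 s
  plan <- segment_plan(180, "unlocked_drift", detuning_pct = 5)
  steps <- generate_steps(beats, plan, timing_noise_sd = 0, seed = 52)
  rpa <- relative_phase_angles(steps, beats)$rpa_deg
  inc <- diff(rpa) %% 360
  # closed form: 360 * detuning/100 per beat (here 18 deg), allowing wrap
  expect_equal(mean(inc), 360 * 5 / 100, tolerance = 1)
})

test_that("uniform segments rarely reject uniformity", {
  set.seed(53)
  beats <- generate_beats(75, 180)
  plan <- segment_plan(180, "unlocked_uniform")
  rejections <- 0L; n_win <- 0L
  for (rep in 1:10) {
    steps <- generate_steps(beats, plan, timing_noise_sd = 0.005)
    rpa <- truncate_series(relative_phase_angles(steps, beats), 180)
    ws <- partition_windows(rpa, 20, 180)
    for (k in 1:9) {
      if (nrow(ws$windows[[k]]) >= 8) {
        n_win <- n_win + 1L
        rejections <- rejections +
          circular_uniformity_test(ws$windows[[k]]$rpa_deg)$reject
      }
    }
  }
  expect_lt(rejections / n_win, 0.10)
})

test_that("locked regimes concentrate the window resultant length", {
  set.seed(54)
  beats <- generate_beats(75, 180)
  plan <- segment_plan(180, "locked", kappa = 8)
  ok <- 0L; n_win <- 0L
  for (rep in 1:5) {
    steps <- generate_steps(beats, plan)
    rpa <- truncate_series(relative_phase_angles(steps, beats), 180)
    ws <- partition_windows(rpa, 20, 180)
    for (k in 1:9) {
      n_win <- n_win + 1L
      ok <- ok + (circular_mean_and_R(ws$windows[[k]]$rpa_deg)$R > 0.7)
    }
  }
  expect_equal(ok, n_win)
})

test_that("generated steps are strictly increasing within the trial span", {
  set.seed(55)
  for (rep in 1:10) {
    plan <- default_plan_sampler(180)
    beats <- generate_beats(75, 180)
    steps <- generate_steps(beats, plan)
    expect_true(all(diff(steps$times) > 0))
    expect_true(all(steps$times >= 0 & steps$times < 180))
  }
})

test_that("default cadence yields 20-30 steps per window", {
  set.seed(56)
  sim <- simulate_trial(make_meta(), segment_plan(180, "locked"))
  isi_w <- partition_windows(
    truncate_series(inter_step_intervals(sim$trial$steps)), 20, 180)
  counts <- window_counts(isi_w)
  expect_true(all(counts >= 20 & counts <= 30))
})

test_that("ground truth follows majority window occupancy", {
  plan <- segment_plan(180, c("locked", "unlocked_uniform", "locked"),
                       breaks = c(60, 120))
  gt <- ground_truth_labels(plan, 20, 180)
  expect_equal(gt$true_label,
               rep(c("locked", "unlocked", "locked"), each = 3))

  # boundary off the window grid: majority decides
  plan2 <- segment_plan(180, c("locked", "unlocked_uniform"),
                        breaks = 51)  # window 3 spans 40-60: 11 s locked
  gt2 <- ground_truth_labels(plan2, 20, 180)
  expect_equal(gt2$true_label[3], "locked")
  expect_equal(gt2$true_label[4], "unlocked")
})

test_that("trial-set generation is reproducible under a seed", {
  design <- enumerate_design()
  a <- generate_trial_set(design, seed = 57)
  b <- generate_trial_set(design, seed = 57)
  expect_length(a, 14)
  expect_identical(lapply(a, function(x) x$trial$steps$times),
                   lapply(b, function(x) x$trial$steps$times))
  expect_identical(lapply(a, function(x) x$truth),
                   lapply(b, function(x) x$truth))
})

test_that("von Mises sampler hits its mean direction and concentration", {
  set.seed(58)
  a <- rvonmises(4000, mu = 1, kappa = 8)
  expect_true(all(a > -pi & a <= pi))
  m <- circular_mean_and_R(a * 180 / pi)
  expect_equal(m$mean_deg, 1 * 180 / pi, tolerance = 2)
  # R approximates A(kappa) = I1/I0; for kappa 8 about 0.936
  A8 <- besselI(8, 1) / besselI(8, 0)
  expect_equal(m$R, A8, tolerance = 0.02)
  # kappa 0 is circular uniform
  u <- rvonmises(2000, 0, 0)
  expect_lt(circular_mean_and_R(u * 180 / pi)$R, 0.1)
})

test_that("variability dataset generator honours its coefficients exactly at zero noise", {
  recs <- generate_variability_dataset(c("(Intercept)" = 1.2),
                                       n_subjects = 3, subject_sd = 0,
                                       resid_sd = 0, seed = 59)
  expect_true(all(abs(recs$sd_isi - exp(1.2)) < 1e-12))
  expect_equal(nrow(recs), 3 * 14 * 9)

  # law of large numbers: music - metronome contrast at reference levels
  truth <- c("(Intercept)" = 2.9, "Stimuli: music" = 0.2254)
  big <- generate_variability_dataset(truth, n_subjects = 100,
                                      subject_sd = 0.1, resid_sd = 0.2,
                                      seed = 60)
  ref <- big[big$tempo_offset == 0, ]
  gap <- mean(log(ref$sd_isi[ref$stimulus == "music"])) -
    mean(log(ref$sd_isi[ref$stimulus == "metronome"]))
  expect_lt(abs(gap - 0.2254), 0.03)

  # reproducibility
  r1 <- generate_variability_dataset(truth, n_subjects = 5, seed = 61)
  r2 <- generate_variability_dataset(truth, n_subjects = 5, seed = 61)
  expect_identical(r1, r2)
})
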