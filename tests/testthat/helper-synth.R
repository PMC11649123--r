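# Shared fixtures for the suite: small deterministic trials and a
# brute-force circular-range oracle independent of the package's
# implementation.

# exhaustive gap search: rotate each angle to the start and measure the
# arc needed to cover all points from there
brute_circular_range <- function(angles_deg) {
  a <- sort(angles_deg %% 360)
  n <- length(a)
  spans <- vapply(seq_len(n), function(i) {
    rot <- sort((a - a[i]) %% 360)
    max(rot)
  }, numeric(1))
  min(spans)
}

# two-pass population-SD oracle
brute_window_sd <- function(v) {
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / length(v))
}

# a flat-rPA windowed series: n_win windows, each m i.i.d. N(0, sd) angles
flat_windowed_rpa <- function(n_win = 9, m = 25, sd = 20,
                              window_length = 20) {
  times <- unlist(lapply(seq_len(n_win), function(k)
    (k - 1) * window_length + seq(0.1, window_length - 0.1,
                                  length.out = m)))
  df <- data.frame(time_s = times,
                   rpa_deg = stats::rnorm(n_win * m, 0, sd))
  partition_windows(df, window_length, n_win * window_length)
}

make_meta <- function(subject = "S01", stimulus = "metronome", tempo = 0L)
  trial_meta(subject, stimulus, tempo, baseline_cadence = 75)
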