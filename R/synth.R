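#' Sample from the von Mises distribution
#'
#' Best–Fisher rejection sampler. Used for phase jitter in locked walking
#' segments; `kappa = 0` reduces to the circular uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in radians on `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9)
    return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- atan2(sin(theta), cos(theta))
      i <- i + 1L
    }
  }
  out
}

#' Segment plan for a synthetic trial
#'
#' Defines the coupling regime over time: an ordered set of segments that
#' tile `[0, duration)`, each locked (steps concentrated at a mean phase
#' offset with von Mises jitter), drifting (step period detuned from the
#' beat period, so the phase advances and wraps), or uniform (step phase
#' uniform on each beat interval).
#'
#' @param duration Trial duration in seconds.
#' @param regimes Character vector of regimes, one per segment, values in
#'   `{"locked", "unlocked_drift", "unlocked_uniform"}`.
#' @param breaks Interior segment boundaries in seconds (sorted, strictly
#'   inside `(0, duration)`); `length(regimes) - 1` values.
#' @param offset_deg Mean phase offset of locked segments in degrees
#'   (default -30: footfall slightly before the beat).
#' @param kappa Von Mises concentration of locked segments (default 8).
#' @param detuning_pct Percent period detuning of drift segments
#'   (default 4).
#' @return Object of class `segment_plan`: data frame with columns
#'   `start`, `end`, `regime`, `offset_deg`, `kappa`, `detuning_pct`.
#' @examples
#' segment_plan(180, c("locked", "unlocked_uniform", "locked"),
#'              breaks = c(60, 120))
#' @export
segment_plan <- function(duration, regimes, breaks = NULL,
                         offset_deg = -30, kappa = 8, detuning_pct = 4) {
  regimes <- match.arg(regimes,
                       c("locked", "unlocked_drift", "unlocked_uniform"),
                       several.ok = TRUE)
  if (is.null(breaks)) breaks <- numeric(0)
  if (length(breaks) != length(regimes) - 1L)
    stop("need length(regimes) - 1 interior breaks", call. = FALSE)
  if (length(breaks) && (is.unsorted(breaks, strictly = TRUE) ||
                         any(breaks <= 0 | breaks >= duration)))
    stop("breaks must be strictly increasing inside (0, duration)",
         call. = FALSE)
  edges <- c(0, breaks, duration)
  structure(data.frame(start = edges[-length(edges)], end = edges[-1],
                       regime = regimes,
                       offset_deg = offset_deg, kappa = kappa,
                       detuning_pct = detuning_pct,
                       stringsAsFactors = FALSE),
            class = c("segment_plan", "data.frame"))
}

#' Generate an isochronous beat stream
#'
#' Beats at `k * 60 / tempo_bpm` for `k = 0, 1, ...` while strictly below
#' `duration`.
#'
#' @param tempo_bpm Tempo in beats per minute (> 0).
#' @param duration Duration in seconds.
#' @return An [event_series()] of kind `"beat"`.
#' @examples
#' length(generate_beats(60, 10))  # 10 beats at 0..9 s
#' @export
generate_beats <- function(tempo_bpm, duration = 180) {
  stopifnot(tempo_bpm > 0, duration > 0)
  ibi <- 60 / tempo_bpm
  k <- 0:floor(duration / ibi + 1e-9)
  times <- k * ibi
  # strictly below duration; guard against accumulated rounding at k*ibi
  event_series("beat", times[times < duration - 1e-9])
}

#' Generate a step stream following a segment plan
#'
#' Produces footfall times coupled to (or decoupled from) a beat stream
#' according to the plan:
#' * **locked**: one step per beat at phase `offset_deg` plus von Mises
#'   jitter of concentration `kappa`, mapped to time through the local
#'   inter-beat interval, plus Gaussian timing noise;
#' * **unlocked_drift**: isochronous steps with period
#'   `IBI * (1 + detuning_pct/100)`, so the phase advances about
#'   `3.6 * detuning_pct` degrees per beat and wraps;
#' * **unlocked_uniform**: one step per beat interval at an i.i.d. uniform
#'   phase.
#'
#' The merged stream is sorted and strictly increasing; collisions from
#' jitter are resolved by a minimal separation.
#'
#' @param beats An [event_series()] of beats (or numeric beat times).
#' @param plan A [segment_plan()] tiling the beat stream's span.
#' @param timing_noise_sd SD of additive Gaussian timing noise in seconds
#'   (default 0.005).
#' @param seed Optional integer seed for reproducibility.
#' @param min_sep Minimal separation enforced between steps (seconds).
#' @return An [event_series()] of kind `"step"`.
#' @export
generate_steps <- function(beats, plan, timing_noise_sd = 0.005,
                           seed = NULL, min_sep = 1e-3) {
  bt <- if (inherits(beats, "event_series")) beats$times else
    as.numeric(beats)
  stopifnot(inherits(plan, "segment_plan"), length(bt) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ibis <- diff(bt)
  times <- numeric(0)
  for (g in seq_len(nrow(plan))) {
    seg <- plan[g, ]
    # beat intervals whose start lies in this segment
    jj <- which(bt[-length(bt)] >= seg$start & bt[-length(bt)] < seg$end)
    if (length(jj) == 0L) next
    if (seg$regime == "locked") {
      phase <- seg$offset_deg * pi / 180 +
        rvonmises(length(jj), 0, seg$kappa)
      st <- bt[jj] + (phase / (2 * pi)) * ibis[jj]
    } else if (seg$regime == "unlocked_uniform") {
      st <- bt[jj] + stats::runif(length(jj)) * ibis[jj]
    } else { # unlocked_drift
      period <- mean(ibis[jj]) * (1 + seg$detuning_pct / 100)
      st <- seq(seg$start, seg$end - 1e-9, by = period)
    }
    if (timing_noise_sd > 0)
      st <- st + stats::rnorm(length(st), 0, timing_noise_sd)
    times <- c(times, st)
  }
  times <- sort(times)
  times <- times[times >= 0 & times < max(bt)]
  # resolve collisions by pushing forward minimally
  if (length(times) > 1L)
    for (i in 2:length(times))
      if (times[i] - times[i - 1] < min_sep)
        times[i] <- times[i - 1] + min_sep
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("generated step stream is not strictly increasing", call. = FALSE)
  event_series("step", times)
}

#' Ground-truth window labels from a segment plan
#'
#' The true label of each window is decided by majority occupancy: a
#' window is locked when more than half of its duration lies inside
#' locked segments.
#'
#' @param plan A [segment_plan()].
#' @param window_length Window length in seconds.
#' @param total_length Total length in seconds.
#' @return Data frame with `window_index` and `true_label`.
#' @export
ground_truth_labels <- function(plan, window_length = 20,
                                total_length = 180) {
  stopifnot(inherits(plan, "segment_plan"))
  n_win <- as.integer(round(total_length / window_length))
  lab <- vapply(seq_len(n_win), function(k) {
    w0 <- (k - 1) * window_length; w1 <- k * window_length
    locked_time <- sum(pmax(0, pmin(plan$end, w1) - pmax(plan$start, w0)) *
                         (plan$regime == "locked"))
    if (locked_time > window_length / 2) "locked" else "unlocked"
  }, character(1))
  data.frame(window_index = seq_len(n_win), true_label = lab,
             stringsAsFactors = FALSE)
}

#' Simulate one trial with known ground truth
#'
#' Beats at the tempo implied by the metadata
#' (`baseline_cadence * (1 + tempo_offset/100)` bpm), steps by
#' [generate_steps()] under the plan, ground truth by majority window
#' occupancy.
#'
#' @param meta A [trial_meta()].
#' @param plan A [segment_plan()] tiling `[0, duration)`.
#' @param duration Trial duration in seconds (default 180).
#' @param timing_noise_sd Gaussian timing noise SD in seconds.
#' @param seed Optional integer seed.
#' @param window_length Window length used for the truth labels.
#' @return List with `trial` (a [trial()]) and `truth` (data frame of
#'   per-window true labels).
#' @export
simulate_trial <- function(meta, plan, duration = 180,
                           timing_noise_sd = 0.005, seed = NULL,
                           window_length = 20) {
  stopifnot(inherits(meta, "trial_meta"))
  bpm <- meta$baseline_cadence * (1 + meta$tempo_offset / 100)
  beats <- generate_beats(bpm, duration)
  steps <- generate_steps(beats, plan, timing_noise_sd = timing_noise_sd,
                          seed = seed)
  list(trial = trial(meta, steps, beats, duration = duration),
       truth = ground_truth_labels(plan, window_length = window_length,
                                   total_length = duration))
}

#' Default sampler of segment plans
#'
#' Draws a plan of three 60-second segments (boundaries aligned with the
#' 20-second window grid). Each segment is locked with probability 1/2;
#' otherwise it is uniform-phase or drifting with equal probability. The
#' locked regime uses von Mises concentration 8 at mean offset -30
#' degrees; drift segments detune the step period by a sign-random 4-6%.
#'
#' @param duration Trial duration in seconds.
#' @return A [segment_plan()].
#' @export
default_plan_sampler <- function(duration = 180) {
  n_seg <- 3L
  regimes <- ifelse(stats::runif(n_seg) < 0.5, "locked",
                    ifelse(stats::runif(n_seg) < 0.5,
                           "unlocked_uniform", "unlocked_drift"))
  det <- sample(c(-1, 1), 1) * stats::runif(1, 4, 6)
  segment_plan(duration, regimes,
               breaks = duration * seq_len(n_seg - 1L) / n_seg,
               offset_deg = -30, kappa = 8, detuning_pct = det)
}

#' Simulate a set of trials over a design
#'
#' One trial per design record, each with a plan drawn from
#' `plan_sampler`, reproducible under `seed`.
#'
#' @param design List of [trial_meta()] records (e.g. from
#'   [enumerate_design()]).
#' @param plan_sampler Function `(duration) -> segment_plan`.
#' @param seed Integer seed governing all randomness.
#' @param duration,timing_noise_sd,window_length Passed to
#'   [simulate_trial()].
#' @return List of elements `list(trial =, truth =)`, one per design row.
#' @export
generate_trial_set <- function(design, plan_sampler = default_plan_sampler,
                               seed = 1, duration = 180,
                               timing_noise_sd = 0.005, window_length = 20) {
  stopifnot(length(design) >= 1L)
  set.seed(seed)
  lapply(design, function(meta) {
    plan <- plan_sampler(duration)
    simulate_trial(meta, plan, duration = duration,
                   timing_noise_sd = timing_noise_sd, seed = NULL,
                   window_length = window_length)
  })
}

#' Simulate variability records from the log-SD model
#'
#' Generates per-window SD records directly from the linear predictor of
#' the variability model: subject intercepts and residuals are Gaussian,
#' the linear predictor is built from the supplied coefficients on the
#' log scale and exponentiated to SDs. Lock labels are assigned at random
#' per window. Used for parameter-recovery checks of
#' [fit_variability_model()].
#'
#' @param coefficients Named numeric vector on the log scale. Recognised
#'   names: `"(Intercept)"`, `"Tempi: <lvl>"`, `"Stimuli: music"`,
#'   `"Window_lab_resc"`, `"Lock_lab: unlocked"` and interactions joined
#'   by `" * "` (the same dialect the fit reports). Unlisted terms are 0.
#' @param n_subjects Number of subjects (default 12).
#' @param design Design per subject, a list of [trial_meta()] (default
#'   the 14-condition cross).
#' @param n_windows Windows per trial (default 9).
#' @param subject_sd SD of the subject random intercept (default 0.15).
#' @param resid_sd Residual SD (default 0.2).
#' @param p_unlocked Probability a window is labelled unlocked
#'   (default 0.5).
#' @param seed Integer seed.
#' @return Data frame of variability records (same columns as
#'   [merge_labels()] output).
#' @export
generate_variability_dataset <- function(coefficients = c("(Intercept)" = 2.97),
                                         n_subjects = 12,
                                         design = NULL,
                                         n_windows = 9,
                                         subject_sd = 0.15, resid_sd = 0.2,
                                         p_unlocked = 0.5, seed = 1) {
  set.seed(seed)
  if (is.null(design)) design <- enumerate_design()
  subj <- sprintf("S%02d", seq_len(n_subjects))
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  names(u) <- subj
  getc <- function(nm) if (nm %in% names(coefficients))
    unname(coefficients[nm]) else 0
  rows <- list(); i <- 0L
  for (s in subj) for (m in design) for (k in seq_len(n_windows)) {
    i <- i + 1L
    lock <- if (stats::runif(1) < p_unlocked) "unlocked" else "locked"
    tl <- tempo_label(m$tempo_offset)
    eta <- getc("(Intercept)") + u[[s]] +
      getc("Window_lab_resc") * (k / 10)
    if (tl != "0") eta <- eta + getc(paste0("Tempi: ", tl))
    if (m$stimulus == "music") eta <- eta + getc("Stimuli: music")
    if (lock == "unlocked") eta <- eta + getc("Lock_lab: unlocked")
    if (tl != "0" && m$stimulus == "music")
      eta <- eta + getc(sprintf("Tempi: %s * Stimuli: music", tl))
    if (tl != "0" && lock == "unlocked")
      eta <- eta + getc(sprintf("Tempi: %s * Lock_lab: unlocked", tl))
    eta <- eta + stats::rnorm(1, 0, resid_sd)
    rows[[i]] <- data.frame(subject_id = s, stimulus = m$stimulus,
                            tempo_offset = m$tempo_offset,
                            window_index = k, window_rescaled = k / 10,
                            lock_label = lock, sd_isi = exp(eta),
                            n_steps = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
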