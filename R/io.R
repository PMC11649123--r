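#' Trial metadata
#'
#' Describes one walking trial: who walked, which auditory stimulus was
#' played, and at which tempo offset from the subject's baseline cadence.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param stimulus One of `"metronome"` or `"music"`.
#' @param tempo_offset Signed integer percent offset of the stimulus tempo
#'   from baseline cadence; one of -12, -8, -4, 0, 4, 8, 12.
#' @param baseline_cadence Baseline comfortable cadence in steps per minute
#'   (positive). The stimulus tempo is
#'   `baseline_cadence * (1 + tempo_offset/100)` beats per minute.
#' @param strict Enforce the standard protocol levels (two stimuli, seven
#'   tempi; default `TRUE`). With `strict = FALSE` any stimulus string and
#'   integer offset are accepted, e.g. for non-standard designs.
#' @return An object of class `trial_meta`.
#' @examples
#' trial_meta("S01", "music", -8, baseline_cadence = 75)
#' @export
trial_meta <- function(subject_id, stimulus, tempo_offset,
                       baseline_cadence = 75, strict = TRUE) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.character(stimulus), length(stimulus) == 1L)
  if (strict) {
    stimulus <- match.arg(stimulus, c("metronome", "music"))
    if (!tempo_offset %in% c(-12L, -8L, -4L, 0L, 4L, 8L, 12L))
      stop("tempo_offset must be one of -12, -8, -4, 0, 4, 8, 12",
           call. = FALSE)
  }
  if (!is.numeric(baseline_cadence) || baseline_cadence <= 0)
    stop("baseline_cadence must be a positive number", call. = FALSE)
  structure(
    list(subject_id = subject_id, stimulus = stimulus,
         tempo_offset = as.integer(tempo_offset),
         baseline_cadence = as.numeric(baseline_cadence)),
    class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("Trial meta: subject %s, %s, tempo %+d%% of %g spm\n",
              x$subject_id, x$stimulus, x$tempo_offset, x$baseline_cadence))
  invisible(x)
}

#' Tempo level label
#'
#' Renders a signed tempo offset as the compact label used in model output:
#' `n12`/`n8`/`n4` for negative offsets, `0` for the reference, `p4`/`p8`/
#' `p12` for positive offsets.
#'
#' @param tempo_offset Integer vector of percent offsets.
#' @return Character vector of labels.
#' @export
tempo_label <- function(tempo_offset) {
  ifelse(tempo_offset == 0, "0",
         paste0(ifelse(tempo_offset < 0, "n", "p"), abs(tempo_offset)))
}

#' Event series
#'
#' An ordered stream of event times (steps or beats) for one trial, in
#' seconds from trial start.
#'
#' @param kind `"step"` or `"beat"`.
#' @param times Numeric vector of non-negative, strictly increasing times.
#' @return An object of class `event_series`.
#' @export
event_series <- function(kind, times) {
  kind <- match.arg(kind, c("step", "beat"))
  times <- as.numeric(times)
  if (length(times) == 0L)
    stop(sprintf("empty %s stream", kind), call. = FALSE)
  if (any(times < 0))
    stop(sprintf("%s times must be non-negative", kind), call. = FALSE)
  d <- diff(times)
  if (length(d) && any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L
    stop(sprintf("%s times not strictly increasing at position %d (t = %g)",
                 kind, row, times[row]), call. = FALSE)
  }
  structure(list(kind = kind, times = times), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("Event series: %d %s events on [%g, %g] s\n",
              length(x$times), x$kind, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

#' A walking trial
#'
#' Bundles trial metadata with its step and beat event streams.
#'
#' @param meta A [trial_meta()] object.
#' @param steps,beats [event_series()] objects of kind `"step"` and
#'   `"beat"` respectively (plain numeric vectors are accepted and wrapped).
#' @param duration Trial duration in seconds (default 180).
#' @return An object of class `trial`.
#' @export
trial <- function(meta, steps, beats, duration = 180) {
  stopifnot(inherits(meta, "trial_meta"), duration > 0)
  if (!inherits(steps, "event_series")) steps <- event_series("step", steps)
  if (!inherits(beats, "event_series")) beats <- event_series("beat", beats)
  stopifnot(steps$kind == "step", beats$kind == "beat")
  structure(list(meta = meta, steps = steps, beats = beats,
                 duration = as.numeric(duration)),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  print(x$meta)
  cat(sprintf("  %d steps, %d beats, duration %g s\n",
              length(x$steps), length(x$beats), x$duration))
  invisible(x)
}

#' Read a trial from a CSV event table
#'
#' The file must be a comma-separated table with a header row and columns
#' `event_kind` (values `step` or `beat`) and `time_s` (seconds from trial
#' start). Events are split by kind; times within each kind must be strictly
#' increasing once sorted (exactly repeated times are rejected).
#'
#' @param path Path to the CSV file.
#' @param meta A [trial_meta()] object for this trial.
#' @param duration Trial duration in seconds.
#' @return A [trial()] object.
#' @seealso [write_trial()]
#' @export
read_trial <- function(path, meta, duration = 180) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_kind", "time_s")
  if (!all(need %in% names(tab)))
    stop(sprintf("trial file %s lacks required columns: %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")),
         call. = FALSE)
  if (!is.numeric(tab$time_s))
    stop(sprintf("trial file %s: time_s is not numeric", path), call. = FALSE)
  pick <- function(kind) {
    t <- sort(tab$time_s[tab$event_kind == kind])
    if (length(t) == 0L)
      stop(sprintf("trial file %s: empty %s stream", path, kind),
           call. = FALSE)
    if (anyDuplicated(t)) {
      row <- which(duplicated(t))[1L]
      stop(sprintf("trial file %s: duplicated %s time %g", path, kind, t[row]),
           call. = FALSE)
    }
    event_series(kind, t)
  }
  trial(meta, pick("step"), pick("beat"), duration = duration)
}

#' Write a trial to a CSV event table
#'
#' Inverse of [read_trial()]: writes the long event table
#' (`event_kind`, `time_s`) with times printed to 6 decimal places.
#'
#' @param x A [trial()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(x, path) {
  stopifnot(inherits(x, "trial"))
  tab <- rbind(
    data.frame(event_kind = "step", time_s = sprintf("%.6f", x$steps$times)),
    data.frame(event_kind = "beat", time_s = sprintf("%.6f", x$beats$times)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enumerate the experimental design
#'
#' Full cross of stimulus and tempo levels, stimuli varying slowest. The
#' two-stimulus by seven-tempo design yields the study's 14 trial
#' conditions per subject.
#'
#' @param stimuli Character vector of stimulus levels (unique).
#' @param tempi Integer vector of tempo offsets (unique).
#' @param subject_id Subject identifier attached to every record.
#' @param baseline_cadence Baseline cadence in steps per minute.
#' @return A list of [trial_meta()] records of length
#'   `length(stimuli) * length(tempi)`.
#' @examples
#' length(enumerate_design())  # 14
#' @export
enumerate_design <- function(stimuli = c("metronome", "music"),
                             tempi = c(-12L, -8L, -4L, 0L, 4L, 8L, 12L),
                             subject_id = "S01",
                             baseline_cadence = 75) {
  if (length(stimuli) == 0L || length(tempi) == 0L)
    stop("stimuli and tempi must be non-empty", call. = FALSE)
  if (anyDuplicated(stimuli)) stop("duplicate stimulus levels", call. = FALSE)
  if (anyDuplicated(tempi)) stop("duplicate tempo levels", call. = FALSE)
  std <- all(stimuli %in% c("metronome", "music")) &&
    all(tempi %in% c(-12L, -8L, -4L, 0L, 4L, 8L, 12L))
  out <- vector("list", length(stimuli) * length(tempi))
  i <- 0L
  for (s in stimuli) for (tp in tempi) {
    i <- i + 1L
    out[[i]] <- trial_meta(subject_id, s, tp, baseline_cadence,
                           strict = std)
  }
  out
}
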