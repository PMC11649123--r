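#' Inter-step intervals
#'
#' The interval series delta_j = Step_{j+1} - Step_j, stamped at the time of
#' the initiating step t_j = Step_j. J step times yield J - 1 intervals.
#'
#' @param steps An [event_series()] of kind `"step"`, or a numeric vector of
#'   strictly increasing step times.
#' @return A data frame with columns `time_s` (stamp of the initiating step)
#'   and `value` (interval in seconds).
#' @examples
#' inter_step_intervals(event_series("step", c(0, 0.5, 1.0, 1.6)))
#' @export
inter_step_intervals <- function(steps) {
  if (inherits(steps, "event_series")) {
    stopifnot(steps$kind == "step")
    t <- steps$times
  } else t <- event_series("step", steps)$times
  if (length(t) < 2L)
    stop("need at least 2 step times to form intervals", call. = FALSE)
  n <- length(t)
  data.frame(time_s = t[-n], value = diff(t))
}

#' Remove interval outliers by the median +/- 3 sd rule
#'
#' A single pass: the median and the sample standard deviation (n - 1
#' denominator) are computed once on the incoming values; observations
#' outside `[median - k*sd, median + k*sd]` are removed. With constant
#' input (sd = 0) nothing is removed.
#'
#' @param series Data frame with columns `time_s`, `value` (as produced by
#'   [inter_step_intervals()]).
#' @param k Multiplier on the standard deviation (default 3).
#' @return The filtered data frame, with a `removal` attribute carrying the
#'   removed row indices, the removed values and the bounds used.
#' @export
remove_outliers <- function(series, k = 3) {
  stopifnot(is.data.frame(series), all(c("time_s", "value") %in% names(series)),
            nrow(series) >= 1L, k > 0)
  v <- series$value
  m <- stats::median(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  lo <- m - k * s
  hi <- m + k * s
  drop <- which(v < lo | v > hi)
  out <- if (length(drop)) series[-drop, , drop = FALSE] else series
  rownames(out) <- NULL
  attr(out, "removal") <- list(indices = drop, values = v[drop],
                               lower = lo, upper = hi,
                               median = m, sd = s)
  out
}

#' Truncate a time-stamped series at a trial-length limit
#'
#' Drops every observation with `time_s >= limit` (half-open convention:
#' the limit itself is excluded). Order is preserved.
#'
#' @param series Data frame with a `time_s` column.
#' @param limit Upper time limit in seconds (default 180).
#' @return The truncated data frame.
#' @export
truncate_series <- function(series, limit = 180) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series), limit > 0)
  out <- series[series$time_s < limit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a time-stamped series into fixed-length windows
#'
#' Divides `[0, total_length)` into `total_length / window_length`
#' consecutive half-open windows `[(k-1)*w, k*w)`, indexed from 1, and
#' assigns each observation by its time stamp: window
#' `floor(time_s / window_length) + 1`. Empty windows are retained. The
#' default 180-s trial with 20-s windows gives nine windows.
#'
#' @param series Data frame with a `time_s` column (other columns carried
#'   along). Observations with `time_s >= total_length` are rejected;
#'   truncate first.
#' @param window_length Window length in seconds (default 20).
#' @param total_length Total series length in seconds (default 180); must be
#'   an exact multiple of `window_length`.
#' @return An object of class `windowed_series`: a list with
#'   `window_length`, `n_windows`, and `windows`, a list of data frames
#'   (one per window, possibly empty) in window order.
#' @examples
#' ws <- partition_windows(data.frame(time_s = c(1, 25, 179)), 20, 180)
#' ws$n_windows  # 9
#' @export
partition_windows <- function(series, window_length = 20, total_length = 180) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series),
            window_length > 0, total_length > 0)
  n_win <- total_length / window_length
  if (abs(n_win - round(n_win)) > 1e-9)
    stop("window_length must divide total_length exactly", call. = FALSE)
  n_win <- as.integer(round(n_win))
  if (nrow(series) && any(series$time_s < 0 | series$time_s >= total_length))
    stop("observations outside [0, total_length); truncate first",
         call. = FALSE)
  idx <- floor(series$time_s / window_length) + 1L
  windows <- lapply(seq_len(n_win), function(k) {
    w <- series[idx == k, , drop = FALSE]
    rownames(w) <- NULL
    w
  })
  structure(list(window_length = window_length, n_windows = n_win,
                 windows = windows),
            class = "windowed_series")
}

#' @export
print.windowed_series <- function(x, ...) {
  counts <- vapply(x$windows, nrow, integer(1))
  cat(sprintf("Windowed series: %d windows of %g s; counts: %s\n",
              x$n_windows, x$window_length, paste(counts, collapse = " ")))
  invisible(x)
}

#' Flatten a windowed series back to a long data frame
#'
#' @param x A `windowed_series`.
#' @param row.names,optional Unused, for S3 compatibility.
#' @param ... Unused.
#' @return Long data frame with a `window_index` column prepended.
#' @export
as.data.frame.windowed_series <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  parts <- lapply(seq_len(x$n_windows), function(k) {
    w <- x$windows[[k]]
    if (nrow(w) == 0L) return(NULL)
    cbind(window_index = k, w)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(window_index = integer(0), time_s = numeric(0))
  rownames(out) <- NULL
  out
}

#' Per-window observation counts
#'
#' @param x A `windowed_series`.
#' @return Integer vector, one count per window.
#' @export
window_counts <- function(x) {
  stopifnot(inherits(x, "windowed_series"))
  vapply(x$windows, nrow, integer(1))
}
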