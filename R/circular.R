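#' Relative phase angles of steps against beats
#'
#' For each step falling inside the beat stream's span, the relative phase
#' angle (rPA) is
#' `360 * (Step_j - Beat_j) / (Beat_{j+1} - Beat_j)` degrees, where `Beat_j`
#' is the last beat at or before the step and `Beat_{j+1}` the next one.
#' The raw phase in `[0, 360)` is mapped to `(-180, 180]` by subtracting
#' 360 when it exceeds 180, so a footfall shortly before a beat carries a
#' negative angle and one shortly after a positive angle. Steps before the
#' first beat or at/after the last beat have no enclosing beat interval and
#' are dropped; their count is recorded in the `dropped` attribute.
#'
#' @param steps,beats [event_series()] objects (or numeric time vectors).
#' @return Data frame with columns `time_s` (step time) and `rpa_deg`, with
#'   attribute `dropped` (number of steps outside the beat span).
#' @examples
#' relative_phase_angles(c(0.9), c(0, 1))  # -36 degrees
#' @export
relative_phase_angles <- function(steps, beats) {
  st <- if (inherits(steps, "event_series")) steps$times else
    event_series("step", steps)$times
  bt <- if (inherits(beats, "event_series")) beats$times else
    event_series("beat", beats)$times
  if (length(bt) < 2L)
    stop("need at least 2 beats to form a beat interval", call. = FALSE)
  if (any(diff(bt) <= 0))
    stop("zero-length or negative beat interval", call. = FALSE)
  # index of the beat at or before each step; 0 if before the first beat
  j <- findInterval(st, bt)
  keep <- j >= 1L & j < length(bt)
  dropped <- sum(!keep)
  stk <- st[keep]; jk <- j[keep]
  raw <- 360 * (stk - bt[jk]) / (bt[jk + 1L] - bt[jk])
  ang <- ifelse(raw > 180, raw - 360, raw)
  out <- data.frame(time_s = stk, rpa_deg = ang)
  attr(out, "dropped") <- dropped
  out
}

#' Circular mean direction and resultant length
#'
#' Mean direction is the angle of the mean unit vector, in degrees on
#' `(-180, 180]`; R is the mean resultant length in `[0, 1]`. When R is
#' numerically zero (e.g. antipodal angles) the mean direction is undefined
#' and reported as `NA`.
#'
#' @param angles_deg Numeric vector of angles in degrees.
#' @param eps Threshold below which R is treated as zero.
#' @return List with `mean_deg` and `R`.
#' @export
circular_mean_and_R <- function(angles_deg, eps = 1e-12) {
  stopifnot(length(angles_deg) >= 1L)
  a <- angles_deg * pi / 180
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  mean_deg <- if (R < eps) NA_real_ else {
    m <- atan2(S, C) * 180 / pi
    if (m <= -180) m + 360 else m
  }
  list(mean_deg = mean_deg, R = R)
}

#' Circular range
#'
#' The length of the smallest arc containing all observations: angles are
#' reduced mod 360 and sorted, circular gaps between neighbours (including
#' the wrap-around gap) are formed, and the range is 360 minus the largest
#' gap. A small range indicates concentration on an arc.
#'
#' @param angles_deg Numeric vector of angles in degrees, length >= 2.
#' @return The circular range in degrees, in `[0, 360)`.
#' @examples
#' circular_range(c(0, 90, 180, 270))  # 270
#' @export
circular_range <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 2L) stop("need at least 2 angles", call. = FALSE)
  a <- sort(angles_deg %% 360)
  gaps <- c(diff(a), a[1L] + 360 - a[n])
  360 - max(gaps)
}

#' Circular-range uniformity test
#'
#' Tests the null hypothesis that angles are uniform on the circle against
#' the alternative that they are concentrated on an arc (no modal direction
#' required). The statistic is the circular range w; the exact null
#' probability of a range at most as small as observed is
#' \deqn{p = \sum_{k=1}^{K} (-1)^{k-1} \binom{n}{k} (1 - k t)^{n-1},}
#' with `t = 1 - w/360` (w in degrees) and `K = floor(1/t)`; terms with
#' `1 - k t <= 0` vanish. Small p means the observations occupy an
#' unusually short arc, i.e. concentration: rejection is evidence of phase
#' locking.
#'
#' @param angles_deg Numeric vector of angles in degrees, length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List of class `circ_uniformity_test` with `statistic` (range in
#'   degrees), `p_value`, `n`, `alpha`, `reject`.
#' @examples
#' circular_uniformity_test(rep(10, 10))$p_value          # 0: maximal concentration
#' circular_uniformity_test(c(0, 90, 180, 270))$p_value   # 1: evenly spread
#' @export
circular_uniformity_test <- function(angles_deg, alpha = 0.05) {
  n <- length(angles_deg)
  if (n < 2L) stop("need at least 2 angles", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  w <- circular_range(angles_deg)
  t <- 1 - w / 360
  p <- if (t <= 0) 1 else {
    K <- min(floor(1 / t), n)
    k <- seq_len(K)
    terms <- (-1)^(k - 1) * choose(n, k) * pmax(1 - k * t, 0)^(n - 1)
    min(max(sum(terms), 0), 1)
  }
  structure(list(statistic = w, p_value = p, n = n, alpha = alpha,
                 reject = p < alpha),
            class = "circ_uniformity_test")
}

#' @export
print.circ_uniformity_test <- function(x, ...) {
  cat(sprintf(paste0("Circular-range uniformity test: range = %.1f deg, ",
                     "n = %d, p = %.4g -> %s\n"),
              x$statistic, x$n, x$p_value,
              if (x$reject) "concentrated (reject uniformity)"
              else "no evidence against uniformity"))
  invisible(x)
}
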