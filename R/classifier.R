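#' Window-specific slope test via a linear mixed model
#'
#' Evaluates the trend of the relative phase angle within each window of a
#' trial. The rPA is regressed on the time since the start of its window,
#' with a window-specific random intercept and random slope:
#' \deqn{rPA = \beta_0 + \beta_1 s + b_0(k) + b_1(k) s + \epsilon,}
#' where `s` is seconds since window start and `k` the window index. The
#' model is fitted by REML over the stacked evaluable windows; each
#' window's predicted slope deviation from the overall slope, the BLUP
#' `b1(k)`, is tested against zero with `z = b1(k) / SE(b1(k))` using the
#' conditional (prediction) standard error and a standard-normal reference.
#' A window whose slope deviates significantly from the trial's overall
#' slope is evidence of unlocking (drift); a flat deviation is evidence of
#' locking.
#'
#' Windows with fewer than `min_obs` observations are excluded from the
#' model and labelled `"unevaluable"`. If the random-slope variance is
#' estimated at the boundary (zero), all deviations are zero and every
#' evaluable window is labelled locked, with a warning.
#'
#' @param windowed_rpa A `windowed_series` of rPA observations (columns
#'   `time_s`, `rpa_deg`), as produced by [partition_windows()].
#' @param alpha Significance level for the per-window test (default 0.05).
#' @param min_obs Minimum observations per window for it to be evaluable
#'   (default 8).
#' @param correlated Logical; if `TRUE` (default) the random intercept and
#'   slope are jointly Gaussian with unstructured 2x2 covariance, otherwise
#'   independent.
#' @param p_adjust Multiple-testing correction across windows, passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return Object of class `slope_test` with a per-window data frame
#'   `windows` (columns `window_index`, `n`, `b1`, `se`, `z`, `p_value`,
#'   `label`), the overall fixed slope `fixed_slope` (deg/s), and
#'   `boundary` (TRUE if the slope variance hit zero).
#' @export
window_slope_test <- function(windowed_rpa, alpha = 0.05, min_obs = 8,
                              correlated = TRUE, p_adjust = "none") {
  stopifnot(inherits(windowed_rpa, "windowed_series"),
            alpha > 0, alpha < 1)
  n_win <- windowed_rpa$n_windows
  counts <- window_counts(windowed_rpa)
  evaluable <- which(counts >= min_obs)
  res <- data.frame(window_index = seq_len(n_win), n = counts,
                    b1 = NA_real_, se = NA_real_, z = NA_real_,
                    p_value = NA_real_,
                    label = rep("unevaluable", n_win),
                    stringsAsFactors = FALSE)
  if (length(evaluable) < 2L)
    stop("need at least 2 evaluable windows for the slope model",
         call. = FALSE)

  stacked <- do.call(rbind, lapply(evaluable, function(k) {
    w <- windowed_rpa$windows[[k]]
    data.frame(window = factor(k, levels = evaluable),
               s = w$time_s - (k - 1) * windowed_rpa$window_length,
               rpa = w$rpa_deg)
  }))

  form <- if (correlated) rpa ~ s + (1 + s | window)
          else rpa ~ s + (1 | window) + (0 + s | window)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = stacked, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e)
      stop(sprintf("slope-model REML fit failed: %s", conditionMessage(e)),
           call. = FALSE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  slope_var <- vc$vcov[which(vc$var1 %in% "s" & is.na(vc$var2) &
                               vc$grp != "Residual")][1]
  resid_var <- vc$vcov[which(vc$grp == "Residual")][1]
  boundary <- isTRUE(slope_var <= 1e-8 * (resid_var + slope_var))

  re <- lme4::ranef(fit, condVar = TRUE)
  b <- NULL
  for (grp in re) if ("s" %in% colnames(grp)) b <- grp
  if (is.null(b) && !correlated) {
    # independent terms: slope lives in its own grouping block
    for (grp in re) if (identical(colnames(grp), "s")) b <- grp
  }
  b1 <- b[["s"]]
  pv_arr <- attr(b, "postVar")
  se1 <- if (is.array(pv_arr) && length(dim(pv_arr)) == 3L) {
    si <- which(colnames(b) == "s")
    sqrt(pv_arr[si, si, ])
  } else sqrt(as.numeric(pv_arr))
  ord <- match(as.character(evaluable), rownames(b))
  b1 <- b1[ord]; se1 <- se1[ord]

  if (boundary) {
    warning("random-slope variance estimated at boundary 0; ",
            "all slope deviations are zero", call. = FALSE)
    b1 <- rep(0, length(evaluable))
    z <- rep(0, length(evaluable))
    p <- rep(1, length(evaluable))
  } else {
    z <- b1 / se1
    p <- 2 * stats::pnorm(-abs(z))
  }
  p <- stats::p.adjust(p, method = p_adjust)

  res$b1[evaluable] <- b1
  res$se[evaluable] <- se1
  res$z[evaluable] <- z
  res$p_value[evaluable] <- p
  res$label[evaluable] <- ifelse(p < alpha, "unlocked", "locked")

  structure(list(windows = res,
                 fixed_slope = unname(lme4::fixef(fit)["s"]),
                 boundary = boundary, alpha = alpha, fit = fit),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("Window slope test (overall slope %.3f deg/s%s):\n",
              x$fixed_slope,
              if (x$boundary) ", slope variance at boundary" else ""))
  print(x$windows[, c("window_index", "n", "b1", "se", "p_value", "label")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Combine fluctuation and trend labels into a final window label
#'
#' A window is finally `"locked"` only when both the circular uniformity
#' evaluation and the slope evaluation say locked; it is `"unlocked"` when
#' either says unlocked; `"unevaluable"` in either input propagates.
#'
#' @param circ,slope Character vectors (recycled to common length) with
#'   values in `{"locked", "unlocked", "unevaluable"}`.
#' @return Character vector of final labels.
#' @examples
#' combine_labels("locked", "unlocked")  # "unlocked"
#' @export
combine_labels <- function(circ, slope) {
  lv <- c("locked", "unlocked", "unevaluable")
  stopifnot(all(circ %in% lv), all(slope %in% lv))
  n <- max(length(circ), length(slope))
  circ <- rep_len(circ, n); slope <- rep_len(slope, n)
  ifelse(circ == "unevaluable" | slope == "unevaluable", "unevaluable",
         ifelse(circ == "locked" & slope == "locked", "locked", "unlocked"))
}

#' Classify the windows of a trial as locked or unlocked
#'
#' Runs the full per-trial labelling pipeline: relative phase angles from
#' the step and beat streams, truncation at the trial duration, partition
#' into fixed-length windows, a circular-range uniformity test per window
#' (rejection = concentration = locked evidence), a linear mixed model
#' slope test across windows (significant deviation from the trial's
#' overall slope = unlocked evidence), and the conjunction rule of
#' [combine_labels()].
#'
#' @param x A [trial()] object.
#' @param window_length Window length in seconds (default 20).
#' @param alpha_circ,alpha_slope Significance levels of the two tests.
#' @param min_obs Minimum observations for a window to be evaluable.
#' @param correlated Random-effects covariance switch, see
#'   [window_slope_test()].
#' @return Object of class `steplock_labels`: a per-window data frame in
#'   `$windows` (columns `window_index`, `n`, `circ_stat`, `circ_p`,
#'   `slope_b1`, `slope_p`, `circ_label`, `slope_label`, `final_label`)
#'   plus `$meta`, `$fixed_slope`, `$alpha`.
#' @examples
#' tr <- simulate_trial(trial_meta("S01", "metronome", 0),
#'                      segment_plan(180, "locked"), seed = 1)
#' classify_trial(tr$trial)
#' @export
classify_trial <- function(x, window_length = 20,
                           alpha_circ = 0.05, alpha_slope = 0.05,
                           min_obs = 8, correlated = TRUE) {
  stopifnot(inherits(x, "trial"))
  rpa <- relative_phase_angles(x$steps, x$beats)
  rpa <- truncate_series(rpa, limit = x$duration)
  ws <- partition_windows(rpa, window_length = window_length,
                          total_length = x$duration)

  counts <- window_counts(ws)
  circ <- lapply(seq_len(ws$n_windows), function(k) {
    if (counts[k] < min_obs) return(list(statistic = NA_real_,
                                         p_value = NA_real_,
                                         label = "unevaluable"))
    ct <- circular_uniformity_test(ws$windows[[k]]$rpa_deg,
                                   alpha = alpha_circ)
    list(statistic = ct$statistic, p_value = ct$p_value,
         label = if (ct$reject) "locked" else "unlocked")
  })

  st <- window_slope_test(ws, alpha = alpha_slope, min_obs = min_obs,
                          correlated = correlated)

  windows <- data.frame(
    window_index = seq_len(ws$n_windows),
    n = counts,
    circ_stat = vapply(circ, `[[`, numeric(1), "statistic"),
    circ_p = vapply(circ, `[[`, numeric(1), "p_value"),
    slope_b1 = st$windows$b1,
    slope_p = st$windows$p_value,
    circ_label = vapply(circ, `[[`, character(1), "label"),
    slope_label = st$windows$label,
    stringsAsFactors = FALSE)
  windows$final_label <- combine_labels(windows$circ_label,
                                        windows$slope_label)

  structure(list(windows = windows, meta = x$meta,
                 fixed_slope = st$fixed_slope,
                 window_length = window_length,
                 alpha = c(circ = alpha_circ, slope = alpha_slope)),
            class = "steplock_labels")
}

#' @export
print.steplock_labels <- function(x, ...) {
  cat(sprintf("Step-to-beat lock classification (%s, %s, tempo %+d%%)\n",
              x$meta$subject_id, x$meta$stimulus, x$meta$tempo_offset))
  print(x$windows[, c("window_index", "n", "circ_p", "slope_p",
                      "circ_label", "slope_label", "final_label")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.steplock_labels <- function(object, ...) {
  tab <- table(factor(object$windows$final_label,
                      levels = c("locked", "unlocked", "unevaluable")))
  cat(sprintf("Final labels: %d locked, %d unlocked, %d unevaluable ",
              tab["locked"], tab["unlocked"], tab["unevaluable"]))
  cat(sprintf("(overall rPA slope %.3f deg/s)\n", object$fixed_slope))
  invisible(tab)
}

#' @export
as.data.frame.steplock_labels <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  cbind(data.frame(subject_id = x$meta$subject_id,
                   stimulus = x$meta$stimulus,
                   tempo_offset = x$meta$tempo_offset),
        x$windows)
}
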