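#' Per-window standard deviation of the inter-step interval
#'
#' The population-denominator standard deviation
#' \deqn{S = \sqrt{\sum_j (\delta_j - \mu)^2 / J},}
#' i.e. dividing by the window's step count J, not J - 1. Windows with
#' fewer than 2 observations are unevaluable and return `NA`.
#'
#' @param values Numeric vector of inter-step intervals in one window.
#' @return The standard deviation (seconds), or `NA_real_` if fewer than 2
#'   values.
#' @examples
#' window_sd(c(0.4, 0.6))  # 0.1
#' @export
window_sd <- function(values) {
  J <- length(values)
  if (J < 2L) return(NA_real_)
  mu <- mean(values)
  sqrt(sum((values - mu)^2) / J)
}

#' Merge window lock labels onto the inter-step-interval windows
#'
#' Transfers the final lock label of each window from a trial
#' classification onto the per-window SD of the inter-step interval,
#' producing the records the variability model consumes. Windows that are
#' unevaluable in either stream (label unevaluable, or fewer than 2
#' intervals) are dropped; the number dropped is recorded in the
#' `dropped` attribute.
#'
#' @param isi_windows A `windowed_series` of cleaned inter-step intervals
#'   (columns `time_s`, `value`), from [partition_windows()].
#' @param labels A `steplock_labels` object for the same trial, produced
#'   with the same window partition.
#' @param meta Optional [trial_meta()]; defaults to the one in `labels`.
#' @return Data frame of variability records: `subject_id`, `stimulus`,
#'   `tempo_offset`, `window_index`, `window_rescaled` (index / 10),
#'   `lock_label`, `sd_isi`, `n_steps`.
#' @export
merge_labels <- function(isi_windows, labels, meta = labels$meta) {
  stopifnot(inherits(isi_windows, "windowed_series"),
            inherits(labels, "steplock_labels"))
  if (isi_windows$n_windows != nrow(labels$windows) ||
      !isTRUE(all.equal(isi_windows$window_length, labels$window_length)))
    stop("window partitions of intervals and labels do not match",
         call. = FALSE)
  recs <- lapply(seq_len(isi_windows$n_windows), function(k) {
    lab <- labels$windows$final_label[k]
    S <- window_sd(isi_windows$windows[[k]]$value)
    if (lab == "unevaluable" || is.na(S)) return(NULL)
    data.frame(subject_id = meta$subject_id, stimulus = meta$stimulus,
               tempo_offset = meta$tempo_offset, window_index = k,
               window_rescaled = k / 10, lock_label = lab, sd_isi = S,
               n_steps = nrow(isi_windows$windows[[k]]),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(recs, is.null, logical(1)))
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# Prepare the model frame: factor coding with the reference levels the
# coefficient table is reported against (tempo 0, metronome, locked).
.variability_frame <- function(records, log_base = exp(1)) {
  need <- c("subject_id", "stimulus", "tempo_offset", "window_rescaled",
            "lock_label", "sd_isi")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (any(records$sd_isi <= 0))
    stop("sd_isi must be positive for the log transform; apply a floor or ",
         "drop zero-SD records first", call. = FALSE)
  tl <- tempo_label(records$tempo_offset)
  lv <- c("0", sort(setdiff(unique(tl), "0")))
  data.frame(
    log_sd = log(records$sd_isi, base = log_base),
    Tempi = factor(tl, levels = lv),
    Stimuli = factor(records$stimulus, levels = c("metronome", "music")),
    Window_resc = records$window_rescaled,
    Lock = factor(records$lock_label, levels = c("locked", "unlocked")),
    subject = factor(records$subject_id))
}

# Rename lme4 coefficient names into the reporting dialect
# (Tempi: n12, Stimuli: music, Lock_lab: unlocked, Window_lab_resc,
# interactions joined by " * ").
.pretty_coef <- function(nm) {
  one <- function(s) {
    s <- sub("^Tempi", "Tempi: ", s)
    s <- sub("^Stimuli", "Stimuli: ", s)
    s <- sub("^Lock", "Lock_lab: ", s)
    s <- sub("^Window_resc$", "Window_lab_resc", s)
    s
  }
  vapply(nm, function(term) {
    # interaction terms arrive as "Tempin12:Stimulimusic"
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    paste(vapply(parts, one, character(1)), collapse = " * ")
  }, character(1), USE.NAMES = FALSE)
}

#' Fit the inter-step-interval variability model
#'
#' Linear mixed model for the log of the per-window SD of the inter-step
#' interval:
#' \deqn{\log S = \beta_0 + Tempi + Stimuli + Window/10 + Lock
#'   + Tempi \times Stimuli + Tempi \times Lock + u_{subject} + \epsilon,}
#' fitted by REML with a subject-level random intercept. Reference levels
#' are tempo 0, stimulus metronome, lock state locked; tempo levels are
#' labelled n12/n8/n4/p4/p8/p12. Fixed-effect p-values use the normal
#' approximation on t = estimate / SE (documented as approximate; no df
#' rule is imposed).
#'
#' @param records Data frame of variability records as produced by
#'   [merge_labels()] (or [generate_variability_dataset()]).
#' @param formula Optional model formula on the prepared frame (response
#'   `log_sd`; terms among `Tempi`, `Stimuli`, `Window_resc`, `Lock` and
#'   interactions; random part fixed at `(1 | subject)`). Defaults to the
#'   main effects plus `Tempi:Stimuli` and `Tempi:Lock`.
#' @param log_base Base of the logarithm (default natural).
#' @param REML Fit by REML (default) or ML.
#' @return Object of class `steplock_varfit` with `coefficients` (data
#'   frame: Parameter, Estimate, Std.error, t, p.value), `ranef_sd`
#'   (subject intercept SD), `resid_sd`, the fitted `lme4` object in
#'   `$fit`, and the `formula` used.
#' @examples
#' \donttest{
#' recs <- generate_variability_dataset(n_subjects = 6, seed = 1)
#' fit_variability_model(recs)
#' }
#' @export
fit_variability_model <- function(records, formula = NULL,
                                  log_base = exp(1), REML = TRUE) {
  df <- .variability_frame(records, log_base = log_base)
  if (length(unique(df$subject)) < 2L)
    stop("need at least 2 subjects for the random intercept", call. = FALSE)
  if (nlevels(droplevels(df$Lock)) < 2L)
    warning("only one lock label present; Lock effects inestimable",
            call. = FALSE)
  if (is.null(formula))
    formula <- log_sd ~ Tempi + Stimuli + Window_resc + Lock +
      Tempi:Stimuli + Tempi:Lock
  full <- stats::update(formula, . ~ . + (1 | subject))
  fit <- lme4::lmer(full, data = df, REML = REML,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(Parameter = .pretty_coef(rownames(sm)),
                      Estimate = sm[, "Estimate"],
                      Std.error = sm[, "Std. Error"],
                      t = sm[, "t value"],
                      p.value = 2 * stats::pnorm(-abs(sm[, "t value"])),
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 ranef_sd = vc$sdcor[which(vc$grp == "subject")][1],
                 resid_sd = vc$sdcor[which(vc$grp == "Residual")][1],
                 formula = formula, REML = REML, n = nrow(df),
                 fit = fit),
            class = "steplock_varfit")
}

#' @export
print.steplock_varfit <- function(x, digits = 4, ...) {
  cat(sprintf("Log-SD variability model (%s, n = %d):\n",
              if (x$REML) "REML" else "ML", x$n))
  tab <- x$coefficients
  tab$Estimate <- round(tab$Estimate, digits)
  tab$Std.error <- round(tab$Std.error, digits)
  tab$t <- round(tab$t, 3)
  tab$p.value <- round(tab$p.value, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Random intercept sd (subject): %.4f; residual sd: %.4f\n",
              x$ranef_sd, x$resid_sd))
  invisible(x)
}

#' @export
summary.steplock_varfit <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.steplock_varfit <- function(object, ...) {
  stats::setNames(object$coefficients$Estimate,
                  object$coefficients$Parameter)
}

#' Backward reduction of the interaction structure
#'
#' Starting from a full mean structure containing the main effects and a
#' set of two-way interaction blocks, repeatedly drops the least
#' significant interaction block (likelihood-ratio test on ML refits)
#' while the weakest block's p-value exceeds `threshold`. Main effects are
#' never dropped. The returned model is refitted by REML.
#'
#' @param records Variability records, as for [fit_variability_model()].
#' @param interactions Character vector of candidate interaction blocks
#'   (default all two-way interactions of Tempi and Lock with the other
#'   covariates, plus `Tempi:Stimuli`).
#' @param threshold Retention threshold for the block LRT (default 0.05).
#' @param log_base Base of the logarithm.
#' @return A `steplock_varfit` for the reduced model, with the retained
#'   interaction blocks in `$retained` and the elimination path in
#'   `$path` (data frame: step, dropped, p.value).
#' @export
model_reduction <- function(records,
                            interactions = c("Tempi:Stimuli", "Tempi:Lock",
                                             "Tempi:Window_resc",
                                             "Stimuli:Lock",
                                             "Lock:Window_resc"),
                            threshold = 0.05, log_base = exp(1)) {
  df <- .variability_frame(records, log_base = log_base)
  main <- "Tempi + Stimuli + Window_resc + Lock"
  build <- function(ints) {
    rhs <- paste(c(main, ints, "(1 | subject)"), collapse = " + ")
    stats::as.formula(paste("log_sd ~", rhs))
  }
  current <- interactions
  path <- data.frame(step = integer(0), dropped = character(0),
                     p.value = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    fit_full <- lme4::lmer(build(current), data = df, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    pvals <- vapply(seq_along(current), function(i) {
      fit_red <- lme4::lmer(build(current[-i]), data = df, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore"))
      as.data.frame(stats::anova(fit_red, fit_full))[2, "Pr(>Chisq)"]
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= threshold) break
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = current[worst],
                                   p.value = pvals[worst]))
    current <- current[-worst]
  }
  rhs <- paste(c(main, current), collapse = " + ")
  out <- fit_variability_model(records,
                               formula = stats::as.formula(
                                 paste("log_sd ~", rhs)),
                               log_base = log_base, REML = TRUE)
  out$retained <- current
  out$path <- path
  out
}
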