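#' Pipeline configuration
#'
#' Collects every tunable of the classification and modelling pipeline in
#' one validated object. Defaults reflect the standard protocol: 180-s
#' trials cut into nine 20-s windows, both tests at level 0.05, the
#' median +/- 3 sd interval outlier rule, at least 8 observations per
#' evaluable window, natural-log SD modelling.
#'
#' @param window_length_s Window length in seconds.
#' @param trial_duration_s Trial duration in seconds.
#' @param alpha_circ,alpha_slope Significance levels of the circular
#'   uniformity test and the slope test.
#' @param outlier_k SD multiplier of the interval outlier rule.
#' @param min_obs_per_window Minimum observations for an evaluable window.
#' @param log_base Base of the log transform in the variability model.
#' @param seed Integer seed for any simulation steps.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_length_s = 20, trial_duration_s = 180,
                            alpha_circ = 0.05, alpha_slope = 0.05,
                            outlier_k = 3, min_obs_per_window = 8,
                            log_base = exp(1), seed = 1) {
  stopifnot(window_length_s > 0, trial_duration_s > 0,
            alpha_circ > 0, alpha_circ < 1,
            alpha_slope > 0, alpha_slope < 1,
            outlier_k > 0, min_obs_per_window >= 2, log_base > 0)
  nw <- trial_duration_s / window_length_s
  if (abs(nw - round(nw)) > 1e-9)
    stop("window_length_s must divide trial_duration_s exactly",
         call. = FALSE)
  structure(list(window_length_s = window_length_s,
                 trial_duration_s = trial_duration_s,
                 alpha_circ = alpha_circ, alpha_slope = alpha_slope,
                 outlier_k = outlier_k,
                 min_obs_per_window = min_obs_per_window,
                 log_base = log_base, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Per-trial half of the pipeline: classification labels plus the cleaned,
# windowed inter-step intervals merged into variability records.
.process_trial <- function(tr, config) {
  labels <- classify_trial(tr, window_length = config$window_length_s,
                           alpha_circ = config$alpha_circ,
                           alpha_slope = config$alpha_slope,
                           min_obs = config$min_obs_per_window)
  isi <- inter_step_intervals(tr$steps)
  isi <- remove_outliers(isi, k = config$outlier_k)
  isi <- truncate_series(isi, limit = config$trial_duration_s)
  isi_w <- partition_windows(isi, window_length = config$window_length_s,
                             total_length = config$trial_duration_s)
  list(labels = labels, records = merge_labels(isi_w, labels, tr$meta))
}

#' Run the full analysis pipeline over a set of trials
#'
#' For every trial: classify its windows as locked/unlocked (circular
#' uniformity + slope test), derive, clean and window the inter-step
#' intervals, and merge the lock labels onto the per-window interval SDs.
#' Finally fits the log-SD variability model over all trials' records.
#' Failing trials are reported and skipped rather than aborting the batch.
#'
#' @param trials A list of [trial()] objects (or of `list(trial = ...)`
#'   elements as returned by [generate_trial_set()]).
#' @param config A [pipeline_config()].
#' @param fit_model Logical: fit the variability model (default `TRUE`;
#'   needs >= 2 subjects and both lock labels).
#' @param reduce Logical: run [model_reduction()] instead of the fixed
#'   mean structure.
#' @return Object of class `steplock_pipeline`: `labels` (long data frame
#'   over trials and windows), `records` (variability records), `fit`
#'   (a `steplock_varfit` or `NULL`), and `failures` (named character
#'   vector of per-trial error messages).
#' @export
run_pipeline <- function(trials, config = pipeline_config(),
                         fit_model = TRUE, reduce = FALSE) {
  stopifnot(length(trials) >= 1L, inherits(config, "pipeline_config"))
  labels_list <- list(); records_list <- list()
  failures <- character(0)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (is.list(tr) && !inherits(tr, "trial") && !is.null(tr$trial))
      tr <- tr$trial
    res <- tryCatch(.process_trial(tr, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
      next
    }
    labels_list[[length(labels_list) + 1L]] <- as.data.frame(res$labels)
    if (nrow(res$records))
      records_list[[length(records_list) + 1L]] <- res$records
  }
  if (length(labels_list) == 0L)
    stop("every trial failed; first error: ", failures[[1]], call. = FALSE)
  labels <- do.call(rbind, labels_list)
  records <- if (length(records_list)) do.call(rbind, records_list)
             else data.frame()
  fit <- NULL
  if (fit_model && nrow(records)) {
    fit <- tryCatch({
      pos <- records[records$sd_isi > 0, , drop = FALSE]
      if (reduce) model_reduction(pos, log_base = config$log_base)
      else fit_variability_model(pos, log_base = config$log_base)
    }, error = function(e) {
      warning("variability model not fitted: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  structure(list(labels = labels, records = records, fit = fit,
                 failures = failures, config = config),
            class = "steplock_pipeline")
}

#' @export
print.steplock_pipeline <- function(x, ...) {
  tab <- table(factor(x$labels$final_label,
                      levels = c("locked", "unlocked", "unevaluable")))
  cat(sprintf("Pipeline: %d trials processed, %d failed\n",
              length(unique(paste(x$labels$subject_id, x$labels$stimulus,
                                  x$labels$tempo_offset))),
              length(x$failures)))
  cat(sprintf("Windows: %d locked, %d unlocked, %d unevaluable; %d variability records\n",
              tab["locked"], tab["unlocked"], tab["unevaluable"],
              nrow(x$records)))
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  }
  invisible(x)
}
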