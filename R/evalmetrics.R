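#' Confusion counts of window labels against ground truth
#'
#' The positive class is `"locked"`: a true positive is a window labelled
#' locked that is truly locked; a true negative is a window labelled
#' unlocked that is truly unlocked. Unevaluable labels are excluded and
#' their count reported.
#'
#' @param labels Character vector of final labels
#'   (`locked`/`unlocked`/`unevaluable`).
#' @param truth Character vector of true labels (`locked`/`unlocked`),
#'   same length.
#' @return Object of class `confusion_counts`: list with `TP`, `TN`,
#'   `FP`, `FN`, `excluded`.
#' @export
confusion <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("labels and truth have different lengths", call. = FALSE)
  keep <- labels != "unevaluable"
  if (!any(keep))
    stop("no evaluable windows to score", call. = FALSE)
  l <- labels[keep]; t <- truth[keep]
  stopifnot(all(l %in% c("locked", "unlocked")),
            all(t %in% c("locked", "unlocked")))
  structure(list(TP = sum(l == "locked" & t == "locked"),
                 TN = sum(l == "unlocked" & t == "unlocked"),
                 FP = sum(l == "locked" & t == "unlocked"),
                 FN = sum(l == "unlocked" & t == "locked"),
                 excluded = sum(!keep)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (locked = positive): TP %d, TN %d, FP %d, FN %d",
              x$TP, x$TN, x$FP, x$FN))
  if (x$excluded) cat(sprintf(" (%d unevaluable excluded)", x$excluded))
  cat("\n")
  invisible(x)
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, with locked as positive class. A metric
#' whose denominator is zero is returned as `NA` rather than raising an
#' error.
#'
#' @param counts A [confusion()] object, or a list with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(accuracy, precision, recall)` in
#'   `[0, 1]` (or `NA` where undefined).
#' @examples
#' classification_metrics(list(TP = 3, TN = 4, FP = 1, FN = 0))
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion table", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = safe(TP + TN, total),
    precision = safe(TP, TP + FP),
    recall = safe(TP, TP + FN))
}

#' Cohen's kappa between two binary label streams
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and chance agreement `p_e` from the raters'
#' marginal proportions. When both raters are constant and identical
#' (`p_e = 1`) kappa is undefined and `NA` is returned. As annotation,
#' 0.60-0.79 is conventionally read as moderate and 0.80-0.90 as strong
#' agreement.
#'
#' @param rater_a,rater_b Character (or factor) vectors of labels, same
#'   length >= 2.
#' @return Kappa in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' cohens_kappa(rep(c("locked", "unlocked"), 5),
#'              rep(c("locked", "unlocked"), 5))  # 1
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b))
    stop("label streams have different lengths", call. = FALSE)
  n <- length(rater_a)
  if (n < 2L) stop("need at least 2 paired labels", call. = FALSE)
  lev <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  a <- factor(rater_a, levels = lev)
  b <- factor(rater_b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (1 - p_e < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}
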