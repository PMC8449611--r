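# Confusion-matrix construction and metric arithmetic, plus end-to-end
# scoring of pipeline off-label flags against planted ground truth.

#' Build a confusion matrix from boolean predictions and truth
#'
#' @param predicted,truth Logical vectors of equal positive length.
#' @return Object of class \code{confusion_matrix}: list with \code{tp}
#'   (pred TRUE, truth TRUE), \code{fp} (TRUE, FALSE), \code{fn} (FALSE,
#'   TRUE), \code{tn} (FALSE, FALSE). Cells sum to the input length.
#' @export
confusion_matrix <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length")
  }
  if (!length(predicted)) stop("cannot score zero predictions")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  structure(list(tp = sum(predicted & truth),
                 fp = sum(predicted & !truth),
                 fn = sum(!predicted & truth),
                 tn = sum(!predicted & !truth)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from its four cells
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return \code{confusion_matrix}.
#' @export
confusion_cells <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop("confusion-matrix cells must be non-negative")
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP=", x$tp, " FP=", x$fp, " FN=", x$fn,
      " TN=", x$tn, " (n=", x$tp + x$fp + x$fn + x$tn, ")\n", sep = "")
  invisible(x)
}

#' Derive accuracy/precision/recall/F1 from a confusion matrix
#'
#' Zero denominators yield \code{NA} (undefined), never an error or a silent
#' zero. An all-zero matrix is an error.
#'
#' @param cm \code{confusion_matrix}.
#' @return Object of class \code{metrics_report}: list with \code{accuracy},
#'   \code{precision}, \code{recall}, \code{f1} as proportions in \[0, 1\]
#'   (or NA).
#' @export
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total < 1) stop("confusion matrix has no observations")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  recall <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (cm$tp + cm$tn) / total, precision = precision,
                 recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else paste0(round(100 * v), "%")
  cat("<metrics_report> accuracy=", pct(x$accuracy),
      " precision=", pct(x$precision), " recall=", pct(x$recall),
      " F1=", pct(x$f1), "\n", sep = "")
  invisible(x)
}

#' Score pipeline off-label flags against ground truth
#'
#' Scores one prediction per post: predicted off-label iff any record for the
#' post has \code{off_label = TRUE}. Posts whose ground truth carries no
#' planted drug–indication pair are excluded (they lack the information
#' off-label adjudication needs); posts marked ambiguous are excluded when
#' \code{exclude_ambiguous = TRUE}. A pairable post with no record at all
#' scores as predicted-negative.
#'
#' @param records Off-label record data.frame (see [flag_pairs()]).
#' @param truth Ground-truth data.frame from [generate_synthetic_corpus()].
#' @param exclude_ambiguous Drop ambiguous-marked posts before scoring.
#' @return List with \code{cm} (\code{confusion_matrix}), \code{metrics}
#'   (\code{metrics_report}), \code{n_scored}, \code{n_excluded_ambiguous},
#'   \code{n_excluded_unpairable}.
#' @export
evaluate_end_to_end <- function(records, truth, exclude_ambiguous = FALSE) {
  pairable <- !vapply(truth$planted_pairs, is.null, logical(1))
  n_unpairable <- sum(!pairable)
  scored <- truth[pairable, , drop = FALSE]
  n_ambiguous <- 0L
  if (exclude_ambiguous) {
    n_ambiguous <- sum(scored$ambiguous)
    scored <- scored[!scored$ambiguous, , drop = FALSE]
  }
  if (!nrow(scored)) stop("no scorable posts after exclusions")
  extra <- setdiff(unique(records$post_id), truth$post_id)
  if (length(extra)) {
    stop("truth missing for scored post(s): ", paste(extra, collapse = ", "))
  }
  flagged <- unique(records$post_id[records$off_label])
  predicted <- scored$post_id %in% flagged
  cm <- confusion_matrix(predicted, scored$off_label_truth)
  list(cm = cm, metrics = metrics_from_cm(cm), n_scored = nrow(scored),
       n_excluded_ambiguous = n_ambiguous,
       n_excluded_unpairable = n_unpairable)
}
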