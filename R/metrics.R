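# Evaluation: leave-one-subject-out folds, classification metrics
# (confusion matrix, accuracy, macro precision/recall/F1, binary ROC and
# precision-recall AUCs) and the clinical summary items (number of tic
# areas, tic frequency, paired t-test).

#' Leave-one-subject-out folds
#'
#' One fold per distinct subject: that subject's clips form the test set and
#' all other subjects' clips the training pool, so no person contributes to
#' both sides of any fold.
#'
#' @param subject_ids character vector (duplicates allowed; >= 2 distinct).
#' @return a list of \code{list(train = subjects, test = subject)} folds
#'   covering every subject exactly once.
#' @export
loso_splits <- function(subject_ids) {
  subs <- unique(as.character(subject_ids))
  if (length(subs) < 2L) stopf("leave-one-subject-out needs >= 2 subjects")
  lapply(subs, function(s) list(train = setdiff(subs, s), test = s))
}

auc_roc_trapezoid <- function(scores, labels) {
  # labels: logical/0-1, positive = TRUE; trapezoidal rule over the ROC curve
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(labels[o])
  P <- sum(y); N <- length(y) - P
  if (P == 0 || N == 0) return(NA_real_)
  # step through distinct thresholds
  tps <- cumsum(y); fps <- cumsum(1 - y)
  keep <- c(diff(scores[o]) != 0, TRUE)
  tpr <- c(0, tps[keep] / P); fpr <- c(0, fps[keep] / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

auc_pr_step <- function(scores, labels) {
  # step-wise precision-recall integral (average precision)
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(labels[o])
  P <- sum(y)
  if (P == 0) return(NA_real_)
  tps <- cumsum(y); fps <- cumsum(1 - y)
  prec <- tps / (tps + fps); rec <- tps / P
  keep <- c(diff(scores[o]) != 0, TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  sum(diff(c(0, rec)) * prec)
}

#' Confusion matrix and classification metrics for one evaluation
#'
#' Builds the n_classes x n_classes confusion matrix (rows = true,
#' columns = predicted) and the derived metrics. Precision, recall and F1 are
#' averaged over classes (\code{"macro"} by default, \code{"weighted"} by
#' true-class support as the alternative); a class never predicted
#' contributes precision 0. For binary problems with scores supplied, the
#' ROC AUC (trapezoidal rule) and precision-recall AUC (step-wise integral)
#' are computed with the tic class as positive.
#'
#' @param y_true,y_pred vectors of labels (character or factor), equal length.
#' @param scores optional matrix of per-class probabilities (columns named by
#'   class) or a vector of positive-class scores for binary problems.
#' @param levels class levels fixing the matrix order; defaults to the sorted
#'   union of observed labels.
#' @param positive positive class for the binary AUCs (default: the non-normal
#'   class).
#' @param average \code{"macro"} or \code{"weighted"}.
#' @return a list of class \code{"fold_report"}: confusion, accuracy,
#'   precision, recall, f1, per_class, and (binary with scores) auc_roc,
#'   auc_pr.
#' @export
confusion_and_metrics <- function(y_true, y_pred, scores = NULL,
                                  levels = NULL, positive = NULL,
                                  average = c("macro", "weighted")) {
  average <- match.arg(average)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred lengths differ (%d vs %d)",
          length(y_true), length(y_pred))
  levels <- levels %||% sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, levels), factor(y_pred, levels))
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) == 0, 0, tp / colSums(cm))
  rec <- ifelse(rowSums(cm) == 0, 0, tp / rowSums(cm))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  w <- if (average == "macro") rep(1 / length(levels), length(levels))
       else rowSums(cm) / sum(cm)
  rep_ <- list(confusion = cm, n = sum(cm),
               accuracy = sum(tp) / sum(cm),
               precision = sum(w * prec), recall = sum(w * rec),
               f1 = sum(w * f1),
               per_class = data.frame(class = levels, precision = prec,
                                      recall = rec, f1 = f1,
                                      support = rowSums(cm)),
               average = average)
  if (!is.null(scores) && length(levels) == 2L) {
    cand <- setdiff(levels, "normal")
    positive <- positive %||% (if (length(cand)) cand[1] else levels[2])
    sc <- if (is.matrix(scores)) scores[, positive] else scores
    rep_$auc_roc <- auc_roc_trapezoid(sc, y_true == positive)
    rep_$auc_pr <- auc_pr_step(sc, y_true == positive)
    rep_$positive <- positive
  }
  structure(rep_, class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("clip classification report (n = %d)\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.4f | %s precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$average, x$precision, x$recall, x$f1))
  if (!is.null(x$auc_roc))
    cat(sprintf("AUC_ROC %.4f | AUC_PR %.4f (positive = %s)\n",
                x$auc_roc, x$auc_pr, x$positive))
  invisible(x)
}

#' Count tic signs in a clip-label sequence
#'
#' A tic sign is one maximal run of consecutive tic-labeled clips (any
#' non-normal label); runs separated by at most \code{gap_tolerance} normal
#' clips are merged into one sign.
#'
#' @param labels chronological clip labels.
#' @param gap_tolerance maximal number of intervening normal clips merged
#'   into a single sign (default 0: plain run-length counting).
#' @return the number of tic signs.
#' @export
count_tic_signs <- function(labels, gap_tolerance = 0L) {
  tic <- as.character(labels) != "normal"
  if (!any(tic)) return(0L)
  pos <- which(tic)
  sum(diff(pos) > gap_tolerance + 1L) + 1L
}

#' Tic frequency in tics per minute
#'
#' @param n_tics number of tic signs observed.
#' @param duration_min video duration in minutes (> 0).
#' @export
tic_frequency <- function(n_tics, duration_min) {
  if (duration_min <= 0) stopf("duration must be positive")
  n_tics / duration_min
}

#' Number of tic areas present in a label sequence
#'
#' The count of distinct tic categories (eye, mouth, ...) occurring among the
#' labels, excluding \code{normal} — the video-scale item scoring how many
#' facial areas are affected.
#'
#' @param labels clip labels from the multiclass task.
#' @export
count_tic_areas <- function(labels) {
  length(setdiff(unique(as.character(labels)), "normal"))
}

#' Two-sided t-test comparing clinician and model rating columns
#'
#' The video-scale comparison treats the clinician and model scores of the
#' rating items as two groups. The default is the two-sample pooled-variance
#' test, which is the form whose p-values the rating-comparison tables of
#' this kind report; \code{paired = TRUE} gives the matched-subjects variant
#' (see \code{\link{paired_ttest}}).
#'
#' @param a,b numeric score vectors (equal length when \code{paired}).
#' @param paired use the paired test on differences instead.
#' @return list(statistic, p.value, df, degenerate).
#' @export
items_ttest <- function(a, b, paired = FALSE) {
  if (paired) return(paired_ttest(a, b))
  if (length(a) < 2L || length(b) < 2L) stopf("t-test needs n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(statistic = 0, p.value = 1,
                df = length(a) + length(b) - 2L, degenerate = TRUE))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Paired two-sided t-test on matched clinical items
#'
#' Compares two matched measurement series (e.g. clinician versus model
#' scores per subject) with a paired t-test on the differences, df = n - 1.
#' When every difference is exactly zero the statistic is degenerate; by
#' convention t = 0, p = 1 is reported with a flag.
#'
#' @param a,b numeric vectors of equal length n >= 2.
#' @return list(statistic, p.value, df, mean_diff, degenerate).
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must have equal length")
  if (length(a) < 2L) stopf("paired t-test needs n >= 2")
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, df = length(a) - 1L,
                mean_diff = 0, degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}
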