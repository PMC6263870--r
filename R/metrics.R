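# Confusion-matrix evaluation: accuracy, macro precision/recall, F1, and
# between-group error counts.

#' Confusion matrix
#'
#' Builds a C x C confusion matrix with a fixed class order. The
#' orientation is rows = predicted labels, columns = true labels: cell
#' \code{(i, j)} counts samples predicted as class \code{i} whose true
#' label is class \code{j}. Row sums are therefore the per-class numbers
#' of inferred labels (NI) and column sums the numbers of true labels
#' (NT).
#'
#' @param true True labels.
#' @param predicted Predicted labels (same length).
#' @param classOrder Fixed class order; defaults to the sorted union of
#'   both label sets. Every label must belong to it.
#' @return A \code{ConfusionMatrix} (an integer matrix subclass).
#' @export
#' @examples
#' m <- confusionMatrix(c("a", "b", "a"), c("a", "b", "b"))
#' m
#' accuracy(m)
confusionMatrix <- function(true, predicted, classOrder = NULL) {
  stopIfNot(
    length(true) == length(predicted),
    "'true' and 'predicted' must have the same length"
  )
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (is.null(classOrder)) classOrder <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), classOrder)
  if (length(bad)) {
    stop(
      "labels outside the class order: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  m <- table(
    factor(predicted, levels = classOrder),
    factor(true, levels = classOrder)
  )
  m <- matrix(as.integer(m), nrow = length(classOrder), dimnames = list(classOrder, classOrder))
  new("ConfusionMatrix", m)
}

#' @describeIn confusionMatrix wrap an already-tabulated square count
#'   matrix (rows = predicted, columns = true)
#' @param counts Square numeric matrix of non-negative integer counts with
#'   identical row and column names.
#' @export
asConfusionMatrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && is.null(colnames(counts))) {
    nm <- paste0("A", seq_len(nrow(counts)))
    dimnames(counts) <- list(nm, nm)
  } else if (is.null(rownames(counts))) {
    rownames(counts) <- colnames(counts)
  } else if (is.null(colnames(counts))) {
    colnames(counts) <- rownames(counts)
  }
  storage.mode(counts) <- "integer"
  new("ConfusionMatrix", counts)
}

.checkNonEmpty <- function(m) {
  stopifnot(is(m, "ConfusionMatrix"))
  stopIfNot(sum(m@.Data) > 0, "the confusion matrix is empty")
}

#' Overall accuracy
#'
#' Fraction of samples on the diagonal: \eqn{\sum_i TP_{ii} / total}.
#'
#' @param m A \code{ConfusionMatrix}.
#' @return Accuracy in \code{[0, 1]}.
#' @export
accuracy <- function(m) {
  .checkNonEmpty(m)
  sum(diag(m@.Data)) / sum(m@.Data)
}

# mean of per-class ratios where a class with a zero denominator
# contributes 0 (kept finite on degenerate predictions).
.macroMean <- function(num, den) {
  ratio <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    message(
      sum(den == 0),
      " class(es) with empty row/column contribute 0 to the macro mean"
    )
  }
  mean(ratio)
}

#' Macro-averaged recall
#'
#' Unweighted mean over classes of \eqn{TP_{ii} / NT_i}, where \eqn{NT_i}
#' is the column (true-label) sum. A class that never occurs contributes
#' 0.
#'
#' @param m A \code{ConfusionMatrix}.
#' @return Macro recall in \code{[0, 1]}.
#' @export
macroRecall <- function(m) {
  .checkNonEmpty(m)
  .macroMean(diag(m@.Data), colSums(m@.Data))
}

#' Macro-averaged precision
#'
#' Unweighted mean over classes of \eqn{TP_{ii} / NI_i}, where \eqn{NI_i}
#' is the row (predicted-label) sum. A class that is never predicted
#' contributes 0.
#'
#' @param m A \code{ConfusionMatrix}.
#' @return Macro precision in \code{[0, 1]}.
#' @export
macroPrecision <- function(m) {
  .checkNonEmpty(m)
  .macroMean(diag(m@.Data), rowSums(m@.Data))
}

#' Macro F1 score
#'
#' Harmonic mean of macro precision and macro recall,
#' \eqn{F1 = 2 P R / (P + R)}; defined as 0 when \eqn{P + R = 0}.
#'
#' @param m A \code{ConfusionMatrix}.
#' @return F1 in \code{[0, 1]}.
#' @export
f1Score <- function(m) {
  p <- macroPrecision(m)
  r <- macroRecall(m)
  if (p + r == 0) {
    return(0)
  }
  2 * p * r / (p + r)
}

#' Between-group error count
#'
#' Counts the samples predicted into one group of activities while truly
#' belonging to a disjoint group: the sum of cells whose predicted label
#' lies in \code{predictedGroup} and whose true label lies in
#' \code{trueGroup}. Because the groups are disjoint no diagonal cell is
#' included.
#'
#' @param m A \code{ConfusionMatrix}.
#' @param predictedGroup,trueGroup Disjoint subsets of the class order.
#' @return Integer error count.
#' @export
#' @examples
#' m <- confusionMatrix(
#'   c("walking", "sitting", "sitting"),
#'   c("walking", "standing", "sitting"),
#'   classOrder = c("walking", "sitting", "standing")
#' )
#' groupErrorCount(m, predictedGroup = "standing", trueGroup = "sitting")
groupErrorCount <- function(m, predictedGroup, trueGroup) {
  stopifnot(is(m, "ConfusionMatrix"))
  cls <- rownames(m@.Data)
  bad <- setdiff(c(predictedGroup, trueGroup), cls)
  if (length(bad)) {
    stop(
      "labels outside the class order: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(intersect(predictedGroup, trueGroup))) {
    stop("'predictedGroup' and 'trueGroup' must be disjoint", call. = FALSE)
  }
  sum(m@.Data[predictedGroup, trueGroup, drop = FALSE])
}

#' Flat metrics report
#'
#' Convenience summary of a confusion matrix as a named numeric vector.
#'
#' @param m A \code{ConfusionMatrix}.
#' @return Named numeric vector with accuracy, macro precision, macro
#'   recall and F1.
#' @export
metricsReport <- function(m) {
  c(
    accuracy = accuracy(m),
    precision = suppressMessages(macroPrecision(m)),
    recall = suppressMessages(macroRecall(m)),
    f1 = suppressMessages(f1Score(m))
  )
}
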