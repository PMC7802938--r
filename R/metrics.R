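#' Pixel-level confusion counts
#'
#' Compares a predicted binary mask against the ground truth pixel by
#' pixel: TP (both 1), FP (predicted 1, truth 0), FN (predicted 0,
#' truth 1), TN (both 0).
#'
#' @param pred,truth H x W matrices with values in \{0, 1\} and identical
#'   dimensions.
#' @return object of class `confusion_counts` with fields tp, fp, fn, tn;
#'   the four counts always sum to the total pixel count.
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop(sprintf("mask dimension mismatch: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(truth), collapse = "x")))
  p <- pred != 0
  t <- truth != 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

degenerate_error <- function(msg) {
  stop(errorCondition(paste("degenerate evaluation:", msg),
                      class = "degenerate_evaluation_error"))
}

#' Precision, recall and F1 score
#'
#' The three pixel-level segmentation quality indicators: precision
#' `P = TP / (TP + FP)`, recall `R = TP / (TP + FN)`, and their harmonic
#' mean `F1 = 2PR / (P + R)`. Undefined denominators raise a
#' `degenerate_evaluation_error` rather than silently returning 0.
#'
#' @param counts a [confusion()] result.
#' @return scalar in \[0, 1\].
#' @examples
#' f1(0.96, 0.98)  # 0.97 to two decimals
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fp == 0)
    degenerate_error("no predicted positives (TP + FP = 0)")
  counts$tp / (counts$tp + counts$fp)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0)
    degenerate_error("no true positives in ground truth (TP + FN = 0)")
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname precision
#' @param x either a `confusion_counts` object or the precision as a
#'   number.
#' @param r recall, when `x` is the precision.
#' @export
f1 <- function(x, r = NULL) {
  if (inherits(x, "confusion_counts")) {
    p <- precision(x)
    r <- recall(x)
  } else {
    p <- x
    if (is.null(r)) stop("supply recall alongside precision")
  }
  if (p + r == 0) degenerate_error("precision + recall = 0")
  2 * p * r / (p + r)
}

#' Evaluate a set of predicted masks
#'
#' Scores every prediction against its ground truth and aggregates both
#' ways: micro (pixel counts pooled across images before computing the
#' metrics -- the headline aggregate) and macro (mean of per-image scores).
#' Images whose per-image metric is undefined (e.g. empty ground truth)
#' get NA in the per-image table and are dropped from the macro mean.
#'
#' @param preds,truths lists of binary masks of equal length.
#' @param ids optional identifiers (default index).
#' @return list with `per_image` (data.frame id, precision, recall, f1),
#'   `micro` and `macro` (named vectors precision/recall/f1).
#' @export
evaluate_masks <- function(preds, truths, ids = NULL) {
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  ids <- ids %||% as.character(seq_along(preds))
  safe <- function(f, cc) tryCatch(f(cc), degenerate_evaluation_error =
                                     function(e) NA_real_)
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion(preds[[i]], truths[[i]])
    p <- safe(precision, cc); r <- safe(recall, cc)
    f <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
    data.frame(id = ids[i], precision = p, recall = r, f1 = f,
               tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn)
  })
  per_image <- do.call(rbind, rows)
  pooled <- structure(list(tp = sum(per_image$tp), fp = sum(per_image$fp),
                           fn = sum(per_image$fn), tn = sum(per_image$tn)),
                      class = "confusion_counts")
  micro <- c(precision = safe(precision, pooled),
             recall = safe(recall, pooled))
  micro["f1"] <- if (anyNA(micro)) NA_real_ else f1(micro[["precision"]],
                                                    micro[["recall"]])
  macro <- c(precision = mean(per_image$precision, na.rm = TRUE),
             recall = mean(per_image$recall, na.rm = TRUE),
             f1 = mean(per_image$f1, na.rm = TRUE))
  list(per_image = per_image[, c("id", "precision", "recall", "f1")],
       micro = micro, macro = macro)
}
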