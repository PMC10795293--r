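#' Match predicted masks to ground truth within a frame set
#'
#' Implements the single-threshold detection evaluation protocol:
#' predictions with confidence below `conf_threshold` are discarded
#' entirely (they count neither as true nor as false positives); the
#' remaining predictions are matched one-to-one to ground-truth masks
#' greedily in descending IoU order, accepting only pairs with IoU at
#' least `iou_threshold`. Unmatched predictions are false positives,
#' unmatched ground truths false negatives — a sub-threshold overlap
#' therefore produces an FP and an FN simultaneously. Ties in IoU go to
#' the lower ground-truth index, then the lower prediction index.
#'
#' @param predictions List of [instance_mask()] objects with confidences
#'   (masks with `NA` confidence are always kept).
#' @param ground_truths List of [instance_mask()] objects.
#' @param conf_threshold Confidence cutoff, default 0.9.
#' @param iou_threshold Minimum IoU for a correct detection, default 0.15.
#' @return An object of class `leaf_detection_match`: `tp_pairs` (tibble
#'   with `pred`, `gt`, `iou`; indices refer to the original input lists),
#'   `fp` and `fn` (integer index vectors), `discarded` (predictions below
#'   the confidence cutoff), and the thresholds used.
#' @export
match_detections <- function(predictions, ground_truths,
                             conf_threshold = 0.9, iou_threshold = 0.15) {
  conf <- vapply(predictions, `[[`, double(1), "confidence")
  keep <- which(is.na(conf) | conf >= conf_threshold)
  discarded <- setdiff(seq_along(predictions), keep)

  m <- iou_matrix(predictions[keep], ground_truths)
  cand <- which(m >= iou_threshold, arr.ind = TRUE)
  tp <- tibble::tibble(pred = integer(0), gt = integer(0), iou = double(0))
  if (nrow(cand)) {
    ious <- m[cand]
    ord <- order(-ious, cand[, 2], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    ious <- ious[ord]
    pred_free <- rep(TRUE, length(keep))
    gt_free <- rep(TRUE, length(ground_truths))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (pred_free[i] && gt_free[j]) {
        pred_free[i] <- FALSE
        gt_free[j] <- FALSE
        tp <- tibble::add_row(tp, pred = keep[i], gt = j, iou = ious[k])
      }
    }
  }
  structure(
    list(tp_pairs = tp,
         fp = setdiff(keep, tp$pred),
         fn = setdiff(seq_along(ground_truths), tp$gt),
         discarded = discarded,
         conf_threshold = conf_threshold,
         iou_threshold = iou_threshold),
    class = "leaf_detection_match"
  )
}

#' @export
print.leaf_detection_match <- function(x, ...) {
  cat(sprintf("<leaf_detection_match> TP %d, FP %d, FN %d (conf >= %.2f, IoU >= %.2f)\n",
              nrow(x$tp_pairs), length(x$fp), length(x$fn),
              x$conf_threshold, x$iou_threshold))
  invisible(x)
}

#' Detection precision, recall and F-score
#'
#' P = TP / (TP + FP), R = TP / (TP + FN), and the F-score is the harmonic
#' mean 2PR / (P + R). Degenerate cases follow the reporting convention:
#' an undefined ratio (zero denominator) is reported as 0 and flagged; if
#' P + R = 0 the F-score is 0.
#'
#' @param match A `leaf_detection_match`, or the TP count when calling with
#'   raw counts.
#' @param fp,fn False-positive / false-negative counts (raw-count form
#'   only).
#' @return An object of class `leaf_metric_report` with fields `precision`,
#'   `recall`, `f_score`, `tp`, `fp`, `fn`, and `flags`.
#' @export
detection_metrics <- function(match, fp = NULL, fn = NULL) {
  if (inherits(match, "leaf_detection_match")) {
    tp <- nrow(match$tp_pairs); fp <- length(match$fp); fn <- length(match$fn)
  } else {
    tp <- match
    if (is.null(fp) || is.null(fn)) {
      stop("raw-count form needs `fp` and `fn`", call. = FALSE)
    }
  }
  if (any(c(tp, fp, fn) < 0) || any(c(tp, fp, fn) != round(c(tp, fp, fn)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  flags <- character(0)
  p <- if (tp + fp > 0) tp / (tp + fp) else {
    flags <- c(flags, "precision undefined (no detections); reported as 0"); 0
  }
  r <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "recall undefined (no ground truths); reported as 0"); 0
  }
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f_score = f,
                 tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 flags = flags),
            class = "leaf_metric_report")
}

#' @export
print.leaf_metric_report <- function(x, ...) {
  cat(sprintf("<leaf_metric_report> P %.4f, R %.4f, F %.4f  (TP %d / FP %d / FN %d)\n",
              x$precision, x$recall, x$f_score, x$tp, x$fp, x$fn))
  for (fl in x$flags) cat(" note:", fl, "\n")
  invisible(x)
}

#' Segmentation quality descriptors over true-positive pairs
#'
#' Summarizes the IoU of matched prediction/ground-truth pairs with the
#' descriptor set count, mean, standard deviation, min, quartiles and max.
#' False positives and negatives are disregarded: the aim is segmentation
#' quality given a correct detection. The standard deviation uses the n-1
#' denominator (0 for a single pair) and quantiles use linear
#' interpolation (`stats::quantile` type 7); both conventions are
#' switchable.
#'
#' @param match A `leaf_detection_match` with at least one TP pair, or a
#'   numeric vector of matched-pair IoUs.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @param quantile_type Passed to [stats::quantile()]; default 7.
#' @return An object of class `leaf_iou_stats` with fields `n`, `mean`,
#'   `std`, `min`, `q25`, `median`, `q75`, `max`.
#' @export
segmentation_iou_stats <- function(match, sd_type = c("sample", "population"),
                                   quantile_type = 7) {
  sd_type <- match.arg(sd_type)
  ious <- if (inherits(match, "leaf_detection_match")) match$tp_pairs$iou else match
  if (!length(ious)) {
    stop("no true-positive pairs: IoU descriptors are undefined", call. = FALSE)
  }
  n <- length(ious)
  std <- if (n == 1L) 0 else stats::sd(ious)
  if (sd_type == "population") std <- std * sqrt((n - 1) / n)
  qs <- stats::quantile(ious, c(0.25, 0.5, 0.75), type = quantile_type,
                        names = FALSE)
  structure(list(n = n, mean = mean(ious), std = std,
                 min = min(ious), q25 = qs[1], median = qs[2], q75 = qs[3],
                 max = max(ious)),
            class = "leaf_iou_stats")
}

#' @export
print.leaf_iou_stats <- function(x, ...) {
  cat(sprintf("<leaf_iou_stats> n %d: mean %.3f +/- %.3f, min %.3f, 25/50/75%% %.3f/%.3f/%.3f, max %.3f\n",
              x$n, x$mean, x$std, x$min, x$q25, x$median, x$q75, x$max))
  invisible(x)
}
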