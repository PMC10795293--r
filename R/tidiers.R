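#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a detection metric report
#'
#' @param x A `leaf_metric_report` from [detection_metrics()].
#' @param ... Unused.
#' @return One-row tibble `tp, fp, fn, precision, recall, f_score`.
#' @exportS3Method generics::tidy
tidy.leaf_metric_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = x$precision, recall = x$recall,
                 f_score = x$f_score)
}

#' Tidy segmentation IoU descriptors
#'
#' @param x A `leaf_iou_stats` from [segmentation_iou_stats()].
#' @param ... Unused.
#' @return Long tibble `descriptor, value` in the order total, mean, STD,
#'   min, 25/50/75%, max.
#' @exportS3Method generics::tidy
tidy.leaf_iou_stats <- function(x, ...) {
  tibble::tibble(
    descriptor = c("total", "mean", "std", "min", "q25", "median", "q75", "max"),
    value = c(x$n, x$mean, x$std, x$min, x$q25, x$median, x$q75, x$max))
}

#' Tidy a detection match
#'
#' @param x A `leaf_detection_match` from [match_detections()].
#' @param ... Unused.
#' @return Tibble `role, pred, gt, iou` with one row per TP pair, FP and
#'   FN.
#' @exportS3Method generics::tidy
tidy.leaf_detection_match <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$tp_pairs, role = "tp", .before = 1),
    tibble::tibble(role = "fp", pred = x$fp, gt = NA_integer_, iou = NA_real_),
    tibble::tibble(role = "fn", pred = NA_integer_, gt = x$fn, iou = NA_real_))
}

#' One-row summary of a detection match
#' @param x A `leaf_detection_match`.
#' @param ... Unused.
#' @return One-row tibble with counts, thresholds and derived metrics.
#' @exportS3Method generics::glance
glance.leaf_detection_match <- function(x, ...) {
  mr <- detection_metrics(x)
  dplyr::mutate(tidy(mr), conf_threshold = x$conf_threshold,
                iou_threshold = x$iou_threshold)
}

#' Tidy per-pair association scores of a HOTA report
#'
#' @param x A `leaf_hota` from [hota_score()].
#' @param ... Unused.
#' @return Tibble `pred_track, gt_track, n_matches, A`.
#' @exportS3Method generics::tidy
tidy.leaf_hota <- function(x, ...) x$assoc

#' One-row summary of a HOTA report
#' @param x A `leaf_hota`.
#' @param ... Unused.
#' @return One-row tibble `hota, alpha, tp, fn, fp`.
#' @exportS3Method generics::glance
glance.leaf_hota <- function(x, ...) {
  tibble::tibble(hota = x$hota, alpha = x$alpha,
                 tp = x$tp, fn = x$fn, fp = x$fp)
}

#' Tidy whole-track verdicts
#'
#' @param x A `leaf_track_verdict` from [classify_tracks()].
#' @param ... Unused.
#' @return The per-leaf verdict tibble.
#' @exportS3Method generics::tidy
tidy.leaf_track_verdict <- function(x, ...) x$verdicts

#' One-row summary of track verdicts
#' @param x A `leaf_track_verdict`.
#' @param ... Unused.
#' @return One-row tibble `n_right, n_miss, n_excluded, fraction_right`.
#' @exportS3Method generics::glance
glance.leaf_track_verdict <- function(x, ...) {
  tibble::tibble(n_right = x$n_right, n_miss = x$n_miss,
                 n_excluded = x$n_excluded, fraction_right = x$fraction_right)
}

#' Tidy a track set
#'
#' @param x A `track_set`.
#' @param ... Unused.
#' @return The long-format [track_table()].
#' @exportS3Method generics::tidy
tidy.track_set <- function(x, ...) track_table(x)

#' One-row summary of a track set
#' @param x A `track_set`.
#' @param ... Unused.
#' @return One-row tibble `plant_id, n_tracks, n_frames, n_observed,
#'   n_carried`.
#' @exportS3Method generics::glance
glance.track_set <- function(x, ...) {
  tab <- track_table(x)
  tibble::tibble(plant_id = x$plant_id, n_tracks = length(x$tracks),
                 n_frames = x$n_frames,
                 n_observed = sum(tab$status != "carried"),
                 n_carried = sum(tab$status == "carried"))
}
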