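# Optimal one-to-one assignment (Hungarian algorithm, O(n^3) potentials
# formulation). Minimizes total cost over full matchings of rows to
# columns; requires nrow(cost) <= ncol(cost). Internal; verified in tests
# against exhaustive permutation enumeration.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  if (n == 0L) return(integer(0))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)        # row potentials (index i)
  v <- numeric(m + 1L)        # col potentials (index j + 1; j = 0 virtual)
  p <- integer(m + 1L)        # p[j + 1] = row matched to column j
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) match_of_row[p[j + 1L]] <- j
  match_of_row
}

# Maximum-weight one-to-one matching between rows and columns of a weight
# matrix, keeping only pairs with weight > 0. Weights below the admissible
# threshold should be zeroed by the caller.
max_weight_matching <- function(w) {
  n <- nrow(w); m <- ncol(w)
  if (n == 0L || m == 0L) {
    return(tibble::tibble(row = integer(0), col = integer(0), weight = double(0)))
  }
  flipped <- n > m
  if (flipped) w <- t(w)
  assign <- solve_assignment(max(w) - w)
  rows <- seq_len(nrow(w))
  keep <- w[cbind(rows, assign)] > 0
  out <- tibble::tibble(row = rows[keep], col = assign[keep],
                        weight = w[cbind(rows[keep], assign[keep])])
  if (flipped) out <- tibble::tibble(row = out$col, col = out$row,
                                     weight = out$weight)
  out
}

# Observed (non-carried) detections of a track set as a per-frame list of
# (track_id, mask) records.
observed_detections <- function(trackset) {
  dets <- vector("list", trackset$n_frames)
  for (f in seq_len(trackset$n_frames)) dets[[f]] <- list()
  for (tr in trackset$tracks) {
    for (e in tr$entries) {
      if (e$status != "carried") {
        f <- e$frame_index + 1L
        dets[[f]][[length(dets[[f]]) + 1L]] <-
          list(track_id = tr$track_id, mask = e$mask)
      }
    }
  }
  dets
}

#' Frame-by-frame correspondence between predicted and ground-truth tracks
#'
#' For every frame, matches predicted observed detections one-to-one to
#' ground-truth detections, maximizing summed IoU subject to each matched
#' pair reaching the localization threshold `alpha` (optimal assignment,
#' not greedy). Carried placeholder entries of the predicted track set are
#' excluded: they are not detections. This is the substrate on which the
#' HOTA metric and the right/miss track verdicts are computed.
#'
#' @param pred,gt `track_set` objects over the same frame range and grid
#'   (`gt` typically from [trackset_from_labels()]).
#' @param alpha Localization threshold in (0, 1]; default 0.5.
#' @return An object of class `leaf_track_correspondence`: `matches`
#'   (tibble `frame_index, pred_track, gt_track, iou`), `pred_dets` and
#'   `gt_dets` (tibbles `frame_index, track_id` of all observed
#'   detections), and `alpha`.
#' @export
build_correspondence <- function(pred, gt, alpha = 0.5) {
  stopifnot(inherits(pred, "track_set"), inherits(gt, "track_set"))
  if (pred$n_frames != gt$n_frames) {
    stop("predicted and ground-truth track sets cover different frame counts",
         call. = FALSE)
  }
  pd <- observed_detections(pred)
  gd <- observed_detections(gt)
  det_tab <- function(dets) {
    purrr::map_dfr(seq_along(dets), function(f) {
      tibble::tibble(
        frame_index = f - 1L,
        track_id = vapply(dets[[f]], `[[`, integer(1), "track_id"))
    })
  }
  matches <- purrr::map_dfr(seq_len(pred$n_frames), function(f) {
    pf <- pd[[f]]; gf <- gd[[f]]
    if (!length(pf) || !length(gf)) {
      return(tibble::tibble(frame_index = integer(0), pred_track = integer(0),
                            gt_track = integer(0), iou = double(0)))
    }
    w <- iou_matrix(lapply(pf, `[[`, "mask"), lapply(gf, `[[`, "mask"))
    w[w < alpha] <- 0
    mm <- max_weight_matching(w)
    tibble::tibble(
      frame_index = f - 1L,
      pred_track = vapply(pf[mm$row], `[[`, integer(1), "track_id"),
      gt_track = vapply(gf[mm$col], `[[`, integer(1), "track_id"),
      iou = mm$weight)
  })
  structure(list(matches = matches,
                 pred_dets = det_tab(pd), gt_dets = det_tab(gd),
                 alpha = alpha),
            class = "leaf_track_correspondence")
}

#' Higher Order Tracking Accuracy (HOTA)
#'
#' Combines detection and association quality in one score:
#' \deqn{HOTA = \sqrt{\frac{\sum_{c \in TP} A(c)}{|TP| + |FN| + |FP|}}}
#' where, for each true-positive match \eqn{c} pairing predicted track i
#' with ground-truth track j, \eqn{TPA(c)} counts the matches with the
#' same (i, j) pairing across all frames, \eqn{FNA(c)} the ground-truth
#' detections of j not so matched, \eqn{FPA(c)} the predicted detections
#' of i not so matched, and
#' \eqn{A(c) = |TPA(c)| / (|TPA(c)| + |FNA(c)| + |FPA(c)|)}.
#'
#' With no detections on either side the score is 1 by convention (and
#' flagged); with ground truth but no true positives it is 0.
#'
#' @param corr A [build_correspondence()] result.
#' @return An object of class `leaf_hota`: `hota`, `alpha`, counts `tp`,
#'   `fn`, `fp`, per-pair association table `assoc` (`pred_track,
#'   gt_track, n_matches, A`), and `flags`.
#' @export
hota_score <- function(corr) {
  stopifnot(inherits(corr, "leaf_track_correspondence"))
  tp <- nrow(corr$matches)
  fn <- nrow(corr$gt_dets) - tp
  fp <- nrow(corr$pred_dets) - tp
  flags <- character(0)
  if (tp + fn + fp == 0L) {
    flags <- "no detections in prediction or ground truth; HOTA = 1 by convention"
    assoc <- tibble::tibble(pred_track = integer(0), gt_track = integer(0),
                            n_matches = integer(0), A = double(0))
    return(structure(list(hota = 1, alpha = corr$alpha, tp = 0L, fn = fn,
                          fp = fp, assoc = assoc, flags = flags),
                     class = "leaf_hota"))
  }
  assoc <- corr$matches |>
    dplyr::count(.data$pred_track, .data$gt_track, name = "n_matches")
  gt_sizes <- dplyr::count(corr$gt_dets, .data$track_id, name = "n_gt")
  pred_sizes <- dplyr::count(corr$pred_dets, .data$track_id, name = "n_pred")
  assoc <- assoc |>
    dplyr::left_join(gt_sizes, by = c(gt_track = "track_id")) |>
    dplyr::left_join(pred_sizes, by = c(pred_track = "track_id")) |>
    dplyr::mutate(
      tpa = .data$n_matches,
      fna = .data$n_gt - .data$n_matches,
      fpa = .data$n_pred - .data$n_matches,
      A = .data$tpa / (.data$tpa + .data$fna + .data$fpa)) |>
    dplyr::select("pred_track", "gt_track", "n_matches", "A")
  hota <- sqrt(sum(assoc$n_matches * assoc$A) / (tp + fn + fp))
  structure(list(hota = hota, alpha = corr$alpha, tp = as.integer(tp),
                 fn = as.integer(fn), fp = as.integer(fp),
                 assoc = assoc, flags = flags),
            class = "leaf_hota")
}

#' @export
print.leaf_hota <- function(x, ...) {
  cat(sprintf("<leaf_hota> HOTA %.4f at alpha %.2f  (TP %d / FN %d / FP %d)\n",
              x$hota, x$alpha, x$tp, x$fn, x$fp))
  for (fl in x$flags) cat(" note:", fl, "\n")
  invisible(x)
}

#' HOTA averaged over a grid of localization thresholds
#'
#' The original HOTA formulation integrates over alpha in
#' `{0.05, 0.10, ..., 0.95}`; this evaluates [hota_score()] at each alpha
#' and averages.
#'
#' @param pred,gt `track_set` objects.
#' @param alphas Thresholds to average over.
#' @return A tibble with one row per alpha plus the mean as attribute
#'   `mean_hota`.
#' @export
hota_alpha_grid <- function(pred, gt, alphas = seq(0.05, 0.95, by = 0.05)) {
  tab <- purrr::map_dfr(alphas, function(a) {
    h <- hota_score(build_correspondence(pred, gt, alpha = a))
    tibble::tibble(alpha = a, hota = h$hota, tp = h$tp, fn = h$fn, fp = h$fp)
  })
  attr(tab, "mean_hota") <- mean(tab$hota)
  tab
}

#' Whole-track right/miss verdicts against ground truth
#'
#' Classifies every ground-truth leaf by whether one predicted track
#' follows it from its first to its last detectable frame with consistent
#' identity. A leaf is excluded from evaluation when it appears in fewer
#' than `min_timepoints` frames or its median detected area falls below
#' `min_area` (transient or degenerate detections). Otherwise the
#' predicted track holding the majority of the leaf's matched detections
#' is taken as its covering track; the leaf is "right" when at most
#' `max_missing` of its detectable frames lack a match to that track, and
#' "miss" otherwise.
#'
#' @param pred,gt `track_set` objects.
#' @param alpha Localization threshold for the underlying per-frame
#'   matching; default 0.5.
#' @param max_missing Maximum tolerated missing detections per leaf,
#'   default 5.
#' @param min_timepoints Minimum appearances for a leaf to be evaluated,
#'   default 4 (leaves seen in 1-3 frames are excluded).
#' @param min_area Minimum median area (pixels) for evaluation, default 5.
#' @return An object of class `leaf_track_verdict`: `verdicts` (tibble
#'   `gt_track, n_detectable, covering_track, n_missed, verdict`), counts
#'   `n_right`, `n_miss`, `n_excluded`, and `fraction_right`.
#' @export
classify_tracks <- function(pred, gt, alpha = 0.5, max_missing = 5L,
                            min_timepoints = 4L, min_area = 5) {
  corr <- build_correspondence(pred, gt, alpha = alpha)
  gt_areas <- purrr::map_dfr(gt$tracks, function(tr) {
    tibble::tibble(
      gt_track = tr$track_id,
      area = vapply(tr$entries, function(e) mask_area(e$mask), integer(1)),
      observed = vapply(tr$entries, function(e) e$status != "carried", logical(1)))
  }) |> dplyr::filter(.data$observed)

  verdicts <- gt_areas |>
    dplyr::group_by(.data$gt_track) |>
    dplyr::summarise(n_detectable = dplyr::n(),
                     median_area = stats::median(.data$area), .groups = "drop")
  per_leaf <- function(gid, n_det, med_area) {
    if (n_det < min_timepoints || med_area < min_area) {
      return(tibble::tibble(gt_track = gid, n_detectable = n_det,
                            covering_track = NA_integer_, n_missed = NA_integer_,
                            verdict = "excluded"))
    }
    mm <- corr$matches[corr$matches$gt_track == gid, ]
    if (!nrow(mm)) {
      return(tibble::tibble(gt_track = gid, n_detectable = n_det,
                            covering_track = NA_integer_, n_missed = n_det,
                            verdict = "miss"))
    }
    tally <- dplyr::count(mm, .data$pred_track) |>
      dplyr::arrange(dplyr::desc(.data$n), .data$pred_track)  # ties: lower id
    cover <- tally$pred_track[1]
    missed <- n_det - tally$n[1]
    tibble::tibble(gt_track = gid, n_detectable = n_det,
                   covering_track = cover, n_missed = missed,
                   verdict = if (missed <= max_missing) "right" else "miss")
  }
  out <- purrr::pmap_dfr(
    list(verdicts$gt_track, verdicts$n_detectable, verdicts$median_area),
    per_leaf)
  n_right <- sum(out$verdict == "right")
  n_miss <- sum(out$verdict == "miss")
  structure(list(verdicts = out, n_right = n_right, n_miss = n_miss,
                 n_excluded = sum(out$verdict == "excluded"),
                 fraction_right = fraction_right(n_right, n_right + n_miss)),
            class = "leaf_track_verdict")
}

#' Fraction of correctly tracked leaves
#'
#' @param n_right Number of leaves tracked end-to-end without identity
#'   loss (within the allowed missing detections).
#' @param n_evaluated Total leaves evaluated (right + miss; excluded
#'   leaves do not count).
#' @return Proportion in `[0, 1]` (`NaN` when nothing was evaluated).
#' @export
fraction_right <- function(n_right, n_evaluated) {
  if (n_evaluated == 0) return(NaN)
  n_right / n_evaluated
}

#' @export
print.leaf_track_verdict <- function(x, ...) {
  cat(sprintf("<leaf_track_verdict> right %d / miss %d / excluded %d (%.1f%% right)\n",
              x$n_right, x$n_miss, x$n_excluded, 100 * x$fraction_right))
  invisible(x)
}
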