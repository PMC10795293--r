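# Independent brute-force oracles. These deliberately avoid the package's
# internal representations: masks are handled as explicit (row, col)
# coordinate sets and every quantity is counted with plain nested loops.

# IoU by explicit pixel-coordinate enumeration.
oracle_iou <- function(a, b) {
  coords <- function(m) {
    mm <- mask_matrix(m)
    keys <- character(0)
    for (r in seq_len(nrow(mm))) {
      for (c in seq_len(ncol(mm))) {
        if (mm[r, c]) keys <- c(keys, paste(r, c))
      }
    }
    keys
  }
  ca <- coords(a); cb <- coords(b)
  inter <- sum(ca %in% cb)
  uni <- length(unique(c(ca, cb)))
  inter / uni
}

# Literal simulation of the greedy association loop: queries in order,
# each claims the remaining target with the highest oracle IoU when it
# reaches the threshold.
oracle_associate <- function(queries, targets, threshold) {
  remaining <- seq_along(targets)
  pairs <- rep(NA_integer_, length(queries))
  for (i in seq_along(queries)) {
    best_j <- NA_integer_
    best_iou <- -1
    for (j in remaining) {
      v <- oracle_iou(queries[[i]], targets[[j]])
      if (v > best_iou) {  # strict: ties keep the lowest index
        best_iou <- v
        best_j <- j
      }
    }
    if (!is.na(best_j) && best_iou >= threshold) {
      pairs[i] <- best_j
      remaining <- setdiff(remaining, best_j)
    }
  }
  list(pairs = pairs, new_targets = remaining)
}

# HOTA by nested loops over the raw match/detection tables, straight from
# the definitions of TPA/FNA/FPA and A(c).
oracle_hota <- function(corr) {
  m <- corr$matches
  tp <- nrow(m)
  fn <- nrow(corr$gt_dets) - tp
  fp <- nrow(corr$pred_dets) - tp
  if (tp + fn + fp == 0) return(1)
  total_A <- 0
  if (tp > 0) {
    for (c in seq_len(tp)) {
      pi <- m$pred_track[c]; gj <- m$gt_track[c]
      tpa <- 0
      for (d in seq_len(tp)) {
        if (m$pred_track[d] == pi && m$gt_track[d] == gj) tpa <- tpa + 1
      }
      fna <- 0
      for (d in seq_len(nrow(corr$gt_dets))) {
        if (corr$gt_dets$track_id[d] == gj) {
          f <- corr$gt_dets$frame_index[d]
          matched_to_pair <- FALSE
          for (e in seq_len(tp)) {
            if (m$frame_index[e] == f && m$gt_track[e] == gj &&
                m$pred_track[e] == pi) {
              matched_to_pair <- TRUE
            }
          }
          if (!matched_to_pair) fna <- fna + 1
        }
      }
      fpa <- 0
      for (d in seq_len(nrow(corr$pred_dets))) {
        if (corr$pred_dets$track_id[d] == pi) {
          f <- corr$pred_dets$frame_index[d]
          matched_to_pair <- FALSE
          for (e in seq_len(tp)) {
            if (m$frame_index[e] == f && m$pred_track[e] == pi &&
                m$gt_track[e] == gj) {
              matched_to_pair <- TRUE
            }
          }
          if (!matched_to_pair) fpa <- fpa + 1
        }
      }
      total_A <- total_A + tpa / (tpa + fna + fpa)
    }
  }
  sqrt(total_A / (tp + fn + fp))
}

# Maximum summed weight over all one-to-one assignments, by exhaustive
# recursion (weights below `alpha` are inadmissible).
oracle_best_matching <- function(w, alpha = 0) {
  n <- nrow(w); m <- ncol(w)
  if (n == 0 || m == 0) return(0)
  best <- 0
  recurse <- function(i, used, total) {
    if (i > n) {
      best <<- max(best, total)
      return()
    }
    recurse(i + 1, used, total)  # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && w[i, j] >= alpha) {
        used[j] <- TRUE
        recurse(i + 1, used, total + w[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

# --- small random fixtures ---------------------------------------------

# Random rectangle mask on a small grid.
random_rect_mask <- function(dim = c(12L, 12L), frame_index = 0L,
                             local_id = 1L, confidence = NA_real_) {
  r0 <- sample.int(dim[1] - 2, 1)
  c0 <- sample.int(dim[2] - 2, 1)
  r1 <- min(dim[1], r0 + sample.int(5, 1))
  c1 <- min(dim[2], c0 + sample.int(5, 1))
  m <- matrix(FALSE, dim[1], dim[2])
  m[r0:r1, c0:c1] <- TRUE
  instance_mask(m, frame_index = frame_index, local_id = local_id,
                confidence = confidence)
}

random_mask_list <- function(n, dim = c(12L, 12L), frame_index = 0L) {
  lapply(seq_len(n), function(k) {
    random_rect_mask(dim, frame_index = frame_index, local_id = k)
  })
}

# Small random prediction/ground-truth track-set pair for HOTA oracle
# checks: <= `max_tracks` tracks over <= `max_frames` frames, with random
# detection dropout and identity scrambling on the prediction side.
random_trackset_pair <- function(max_tracks = 4L, max_frames = 6L,
                                 dim = c(16L, 16L)) {
  n_tracks <- sample.int(max_tracks, 1)
  n_frames <- sample(2:max_frames, 1)
  # disjoint horizontal strips so per-frame matching is unambiguous
  rows <- seq(1, by = 3, length.out = n_tracks)
  gt_frames <- lapply(seq_len(n_frames), function(f) {
    m <- matrix(0L, dim[1], dim[2])
    for (k in seq_len(n_tracks)) {
      c0 <- min(dim[2] - 4L, f)  # slight drift over time
      m[rows[k]:(rows[k] + 1), c0:(c0 + 3)] <- k
    }
    label_frame(m, frame_index = f - 1L)
  })
  gt <- trackset_from_labels(gt_frames)
  # prediction: drop ~20% of detections, scramble ids within a frame
  pred_tracks <- list()
  for (k in seq_len(n_tracks)) {
    pred_tracks[[k]] <- list(track_id = k, birth_frame = 0L, entries = list())
  }
  for (f in seq_len(n_frames)) {
    dets <- masks_from_labels(gt_frames[[f]])
    ids <- vapply(dets, `[[`, integer(1), "local_id")
    keep <- stats::runif(length(dets)) > 0.2
    assign_to <- sample(ids)  # identity scramble
    for (d in seq_along(dets)) {
      if (!keep[d]) next
      tid <- assign_to[d]
      tr <- pred_tracks[[tid]]
      tr$entries[[length(tr$entries) + 1L]] <-
        list(frame_index = f - 1L, mask = dets[[d]], status = "observed")
      pred_tracks[[tid]] <- tr
    }
  }
  pred_tracks <- Filter(function(tr) length(tr$entries) > 0, pred_tracks)
  for (k in seq_along(pred_tracks)) {
    pred_tracks[[k]]$track_id <- k
    pred_tracks[[k]]$birth_frame <- pred_tracks[[k]]$entries[[1]]$frame_index
  }
  pred <- structure(list(tracks = pred_tracks, n_frames = n_frames,
                         dim = dim, plant_id = 1L),
                    class = "track_set")
  list(pred = pred, gt = gt)
}
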