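# build a track_set directly from a per-frame list of (track_id, mask)
manual_trackset <- function(frame_dets, n_frames, dim = c(16L, 16L)) {
  ids <- sort(unique(unlist(lapply(frame_dets, function(fd) {
    vapply(fd, `[[`, integer(1), "track_id")
  }))))
  tracks <- lapply(seq_along(ids), function(k) {
    entries <- list()
    for (f in seq_along(frame_dets)) {
      for (d in frame_dets[[f]]) {
        if (d$track_id == ids[k]) {
          entries[[length(entries) + 1L]] <-
            list(frame_index = f - 1L, mask = d$mask, status = "observed")
        }
      }
    }
    list(track_id = k, birth_frame = entries[[1]]$frame_index,
         entries = entries)
  })
  structure(list(tracks = tracks, n_frames = n_frames, dim = dim,
                 plant_id = 1L),
            class = "track_set")
}

strip16 <- function(rows, cols = 1:6) {
  m <- matrix(FALSE, 16, 16)
  m[rows, cols] <- TRUE
  instance_mask(m)
}

test_that("the assignment solver matches exhaustive permutation search", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(1:5, 1)
      m <- if (n == 5L) 5L else sample(n:5, 1)
      w <- matrix(stats::runif(n * m), n, m)
      got <- leaftracker:::solve_assignment(max(w) - w)
      got_total <- sum(w[cbind(seq_len(n), got)])
      best <- oracle_best_matching(w, alpha = 0)
      expect_equal(got_total, best, tolerance = 1e-9)
    }
  })
})

test_that("correspondence matches identical track sets detection-for-detection", {
  dets <- lapply(1:3, function(f) {
    list(list(track_id = 1L, mask = strip16(1:2)),
         list(track_id = 2L, mask = strip16(5:6)))
  })
  ts <- manual_trackset(dets, 3)
  corr <- build_correspondence(ts, ts, alpha = 0.5)
  expect_equal(nrow(corr$matches), 6L)
  expect_true(all(corr$matches$iou == 1))
  expect_equal(corr$matches$pred_track, corr$matches$gt_track)
})

test_that("an empty prediction leaves every ground-truth detection unmatched", {
  gt <- manual_trackset(lapply(1:2, function(f) {
    list(list(track_id = 1L, mask = strip16(1:2)))
  }), 2)
  empty <- structure(list(tracks = list(), n_frames = 2, dim = c(16L, 16L),
                          plant_id = 1L), class = "track_set")
  corr <- build_correspondence(empty, gt, alpha = 0.5)
  expect_equal(nrow(corr$matches), 0L)
  h <- hota_score(corr)
  expect_equal(h$hota, 0)
  expect_equal(h$fn, 2L)

  mismatch <- structure(list(tracks = list(), n_frames = 3, dim = c(16L, 16L),
                             plant_id = 1L), class = "track_set")
  expect_error(build_correspondence(mismatch, gt), "frame counts")
})

test_that("per-frame matching is optimal under crossed overlaps", {
  # two predictions overlap both ground truths; optimal assignment must
  # pick the pairing maximizing summed IoU, as exhaustive search does
  withr::with_seed(53, {
    for (rep in 1:10) {
      gshift <- sample(0:2, 1)
      gt_dets <- list(list(
        list(track_id = 1L, mask = strip16(2:5, 1:8)),
        list(track_id = 2L, mask = strip16((4 + gshift):(8 + gshift), 1:8))))
      pr_dets <- list(list(
        list(track_id = 1L, mask = strip16(3:6, 1:8)),
        list(track_id = 2L, mask = strip16(5:9, 1:8))))
      pred <- manual_trackset(pr_dets, 1)
      gt <- manual_trackset(gt_dets, 1)
      corr <- build_correspondence(pred, gt, alpha = 0.1)
      w <- iou_matrix(
        lapply(pr_dets[[1]], `[[`, "mask"),
        lapply(gt_dets[[1]], `[[`, "mask"))
      w[w < 0.1] <- 0
      expect_equal(sum(corr$matches$iou), oracle_best_matching(w, 1e-12),
                   tolerance = 1e-9)
    }
  })
})

test_that("HOTA is 1 for perfect tracking and penalizes identity scrambles", {
  dets <- lapply(1:4, function(f) {
    list(list(track_id = 1L, mask = strip16(1:2)),
         list(track_id = 2L, mask = strip16(5:6)))
  })
  ts <- manual_trackset(dets, 4)
  expect_equal(hota_score(build_correspondence(ts, ts, 0.5))$hota, 1)

  # same detections, but predicted identities alternate between frames
  swapped <- lapply(1:4, function(f) {
    if (f %% 2 == 0) {
      list(list(track_id = 2L, mask = strip16(1:2)),
           list(track_id = 1L, mask = strip16(5:6)))
    } else {
      dets[[f]]
    }
  })
  pred <- manual_trackset(swapped, 4)
  corr <- build_correspondence(pred, ts, 0.5)
  h <- hota_score(corr)
  expect_lt(h$hota, 1)
  # every pair has TPA = 2, FNA = 2, FPA = 2 -> A = 1/3; HOTA = sqrt(1/3)
  expect_equal(h$hota, sqrt(1 / 3))
  expect_equal(h$hota, oracle_hota(corr))
})

test_that("HOTA equals the nested-loop oracle on random scrambled pairs", {
  withr::with_seed(77, {
    for (rep in 1:15) {
      pair <- random_trackset_pair()
      corr <- build_correspondence(pair$pred, pair$gt, alpha = 0.5)
      expect_equal(hota_score(corr)$hota, oracle_hota(corr), tolerance = 1e-12)
    }
  })
})

test_that("splitting a correct track never increases HOTA", {
  dets <- lapply(1:6, function(f) {
    list(list(track_id = 1L, mask = strip16(1:2)),
         list(track_id = 2L, mask = strip16(5:6)))
  })
  gt <- manual_trackset(dets, 6)
  split_dets <- lapply(1:6, function(f) {
    list(list(track_id = if (f <= 3) 1L else 3L, mask = strip16(1:2)),
         list(track_id = 2L, mask = strip16(5:6)))
  })
  pred_split <- manual_trackset(split_dets, 6)
  h_full <- hota_score(build_correspondence(gt, gt, 0.5))
  h_split <- hota_score(build_correspondence(pred_split, gt, 0.5))
  expect_lt(h_split$hota, h_full$hota)
  expect_equal(h_split$hota,
               oracle_hota(build_correspondence(pred_split, gt, 0.5)))
})

test_that("empty-vs-empty HOTA is 1 by convention and flagged", {
  empty <- structure(list(tracks = list(), n_frames = 2, dim = c(16L, 16L),
                          plant_id = 1L), class = "track_set")
  h <- hota_score(build_correspondence(empty, empty, 0.5))
  expect_equal(h$hota, 1)
  expect_match(h$flags, "convention")
})

test_that("track verdicts implement right / miss / excluded", {
  # leaf tracked throughout -> right; leaf with 6 misses -> miss;
  # leaf seen twice -> excluded
  n_frames <- 12
  gt_dets <- lapply(seq_len(n_frames), function(f) {
    out <- list(list(track_id = 1L, mask = strip16(1:2)),
                list(track_id = 2L, mask = strip16(5:6)))
    if (f <= 2) out <- c(out, list(list(track_id = 3L, mask = strip16(9:10))))
    out
  })
  gt <- manual_trackset(gt_dets, n_frames)
  pred_dets <- lapply(seq_len(n_frames), function(f) {
    out <- list(list(track_id = 1L, mask = strip16(1:2)))
    if (f > 6) {  # leaf 2 missing in 6 of 12 frames
      out <- c(out, list(list(track_id = 2L, mask = strip16(5:6))))
    }
    out
  })
  pred <- manual_trackset(pred_dets, n_frames)
  v <- classify_tracks(pred, gt, max_missing = 5, min_timepoints = 4)
  expect_equal(v$verdicts$verdict[v$verdicts$gt_track == 1], "right")
  expect_equal(v$verdicts$verdict[v$verdicts$gt_track == 2], "miss")
  expect_equal(v$verdicts$verdict[v$verdicts$gt_track == 3], "excluded")
  expect_equal(v$n_right + v$n_miss + v$n_excluded, 3L)
  expect_equal(v$fraction_right, 0.5)

  expect_equal(fraction_right(162, 191), 162 / 191)
  expect_true(is.nan(fraction_right(0, 0)))
})
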