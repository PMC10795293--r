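#' Tracker configuration
#'
#' @param iou_threshold Minimum IoU for a query mask to claim a target mask
#'   in the next frame. Default 0.15 — low enough to bridge the growth and
#'   slight movement of a leaf between consecutive timepoints (roughly 8 h
#'   apart at most in a chlorophyll-fluorescence phenotyping schedule).
#' @param max_carry Maximum number of consecutive carried (missed) entries
#'   before a track is frozen and stops querying. Default `Inf` (unlimited):
#'   a lost leaf keeps its last mask as a placeholder indefinitely and can
#'   re-attach whenever a detection overlaps it again. Set to `0` for a
#'   no-carry ablation in which a single missed detection ends the track.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(iou_threshold = 0.15, max_carry = Inf) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1) {
    stop("`iou_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(max_carry) || length(max_carry) != 1L || max_carry < 0) {
    stop("`max_carry` must be a non-negative number or Inf", call. = FALSE)
  }
  structure(list(iou_threshold = iou_threshold, max_carry = max_carry),
            class = "tracker_config")
}

#' Associate one frame's queries with the next frame's targets
#'
#' The core greedy association step. Queries (the current masks of live
#' tracks, in track-creation order) are processed one at a time: each
#' claims the still-available target with the highest IoU, provided that
#' IoU reaches the threshold, and the claimed target leaves the pool. A
#' query finding no admissible target is carried (it keeps its own mask).
#' Targets left over after all queries are new detections, reported in
#' their within-frame order. Ties between equal-IoU targets go to the
#' lowest target index so results are reproducible.
#'
#' @param queries,targets Lists of [instance_mask()] objects on one grid.
#' @param config A [tracker_config()].
#' @return An object of class `leaf_association`: list with `pairs`
#'   (integer vector, target index per query, `NA` where carried), `iou`
#'   (IoU of each matched pair, `NA` where carried), `carried` (query
#'   indices), and `new_targets` (unclaimed target indices, in order).
#' @export
associate_frame <- function(queries, targets, config = tracker_config()) {
  nq <- length(queries); nt <- length(targets)
  pairs <- rep(NA_integer_, nq)
  ious <- rep(NA_real_, nq)
  m <- iou_matrix(queries, targets)
  available <- rep(TRUE, nt)
  for (i in seq_len(nq)) {
    if (!any(available)) break
    row <- m[i, ]
    row[!available] <- -1
    best <- which.max(row)  # ties -> lowest index
    if (row[best] >= config$iou_threshold) {
      pairs[i] <- best
      ious[i] <- m[i, best]
      available[best] <- FALSE
    }
  }
  structure(
    list(pairs = pairs, iou = ious,
         carried = which(is.na(pairs)),
         new_targets = which(available)),
    class = "leaf_association"
  )
}

#' Track leaves across a sequence of segmented frames
#'
#' Reconstructs per-leaf tracks from per-frame instance masks by greedy
#' IoU association between consecutive timepoints. Masks of the first
#' frame seed tracks 1..N in within-frame order. For every later frame,
#' each live track's most recent mask queries the frame's detections via
#' [associate_frame()]: matched tracks gain an `observed` entry, unmatched
#' tracks carry their previous mask forward verbatim (`carried` status),
#' and unclaimed detections open new tracks appended after the existing
#' ones. Track ids therefore encode leaf order: the order of emergence and
#' detection over time.
#'
#' @param frames List with one element per timepoint, each a list of
#'   [instance_mask()] objects (a frame may be empty).
#' @param config A [tracker_config()].
#' @param plant_id Identifier recorded on the track set (one track set per
#'   plant).
#' @return An object of class `track_set`.
#' @export
track_sequence <- function(frames, config = tracker_config(), plant_id = 1L) {
  if (!length(frames)) stop("`frames` must hold at least one frame", call. = FALSE)
  dims <- unique(do.call(rbind, unlist(
    lapply(frames, function(fr) lapply(fr, `[[`, "dim")), recursive = FALSE)))
  if (is.matrix(dims) && nrow(dims) > 1L) {
    stop("masks come from inconsistent image grids", call. = FALSE)
  }
  img_dim <- if (is.matrix(dims) && nrow(dims) == 1L) as.integer(dims[1, ]) else NULL

  tracks <- list()
  # live bookkeeping: per track, index of last mask and carry streak
  last_mask <- list()
  carry_streak <- integer(0)
  frozen <- logical(0)

  add_entry <- function(tid, fidx, mask, status) {
    tr <- tracks[[tid]]
    tr$entries[[length(tr$entries) + 1L]] <-
      list(frame_index = fidx, mask = mask, status = status)
    tracks[[tid]] <<- tr
  }
  open_track <- function(fidx, mask, status) {
    tid <- length(tracks) + 1L
    tracks[[tid]] <<- list(track_id = tid, birth_frame = fidx, entries = list())
    add_entry(tid, fidx, mask, status)
    last_mask[[tid]] <<- mask
    carry_streak[tid] <<- 0L
    frozen[tid] <<- FALSE
    tid
  }

  for (k in seq_len(length(frames[[1]]))) {
    open_track(0L, frames[[1]][[k]], "observed")
  }

  for (f in seq_along(frames)[-1]) {
    fidx <- f - 1L
    live <- which(!frozen)
    assoc <- associate_frame(last_mask[live], frames[[f]], config)
    for (q in seq_along(live)) {
      tid <- live[q]
      tgt <- assoc$pairs[q]
      if (!is.na(tgt)) {
        add_entry(tid, fidx, frames[[f]][[tgt]], "observed")
        last_mask[[tid]] <- frames[[f]][[tgt]]
        carry_streak[tid] <- 0L
      } else if (carry_streak[tid] < config$max_carry) {
        add_entry(tid, fidx, last_mask[[tid]], "carried")
        carry_streak[tid] <- carry_streak[tid] + 1L
      } else {
        frozen[tid] <- TRUE
      }
    }
    for (tgt in assoc$new_targets) {
      open_track(fidx, frames[[f]][[tgt]], "new")
    }
  }

  structure(list(tracks = tracks, n_frames = length(frames),
                 dim = img_dim, plant_id = plant_id),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> plant %s: %d track(s) over %d frame(s)\n",
              format(x$plant_id), length(x$tracks), x$n_frames))
  invisible(x)
}

#' Build a track set from ground-truth label frames
#'
#' In ground-truth sequences the label value of a leaf is its stable track
#' id across frames; this reads such a sequence straight into a
#' `track_set` (all entries observed, no carry-forward).
#'
#' @param frames List of [label_frame()] objects in temporal order.
#' @param plant_id Identifier recorded on the track set.
#' @return A `track_set` whose track ids are the distinct labels, renumbered
#'   1..N in order of first appearance (ascending label at ties).
#' @export
trackset_from_labels <- function(frames, plant_id = 1L) {
  if (!length(frames)) stop("`frames` must hold at least one frame", call. = FALSE)
  per_frame <- lapply(frames, masks_from_labels)
  labs <- unlist(lapply(per_frame, function(ms) vapply(ms, `[[`, integer(1), "local_id")))
  first_seen <- vapply(
    split(rep(seq_along(per_frame), lengths(per_frame)), labs), min, numeric(1))
  lab_ids <- as.integer(names(first_seen))
  order_labs <- lab_ids[order(first_seen, lab_ids)]
  tracks <- vector("list", length(order_labs))
  for (k in seq_along(order_labs)) {
    lab <- order_labs[k]
    entries <- list()
    for (f in seq_along(per_frame)) {
      ms <- per_frame[[f]]
      hit <- which(vapply(ms, `[[`, integer(1), "local_id") == lab)
      if (length(hit)) {
        status <- if (length(entries)) "observed" else if (f == 1L) "observed" else "new"
        entries[[length(entries) + 1L]] <-
          list(frame_index = f - 1L, mask = ms[[hit]], status = status)
      }
    }
    tracks[[k]] <- list(track_id = k, birth_frame = entries[[1]]$frame_index,
                        entries = entries)
  }
  structure(list(tracks = tracks, n_frames = length(frames),
                 dim = frames[[1]]$dim, plant_id = plant_id),
            class = "track_set")
}

#' Tidy long-format table of a track set
#'
#' @param trackset A `track_set`.
#' @return A tibble with one row per track entry: `plant_id, track_id,
#'   frame_index, status, area, centroid_row, centroid_col`, ordered by
#'   track then frame.
#' @export
track_table <- function(trackset) {
  stopifnot(inherits(trackset, "track_set"))
  rows <- purrr::map_dfr(trackset$tracks, function(tr) {
    purrr::map_dfr(tr$entries, function(e) {
      ctr <- mask_centroid(e$mask)
      tibble::tibble(
        plant_id = trackset$plant_id,
        track_id = tr$track_id,
        frame_index = e$frame_index,
        status = e$status,
        area = mask_area(e$mask),
        centroid_row = unname(ctr["row"]),
        centroid_col = unname(ctr["col"])
      )
    })
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(plant_id = character(0), track_id = integer(0),
                           frame_index = integer(0), status = character(0),
                           area = integer(0), centroid_row = double(0),
                           centroid_col = double(0))
  }
  dplyr::arrange(rows, .data$track_id, .data$frame_index)
}

#' Render a track set back to label frames
#'
#' Pixel value = track id, for visual inspection of tracking results.
#' Carried entries are skipped (they are placeholders, not detections);
#' where observed masks overlap, the higher track id (younger leaf) wins.
#'
#' @param trackset A `track_set`.
#' @param include_carried Paint carried placeholder masks too (default
#'   `FALSE`).
#' @return List of [label_frame()] objects, one per frame.
#' @export
trackset_to_labels <- function(trackset, include_carried = FALSE) {
  stopifnot(inherits(trackset, "track_set"), !is.null(trackset$dim))
  out <- lapply(seq_len(trackset$n_frames) - 1L, function(fidx) {
    m <- matrix(0L, trackset$dim[1], trackset$dim[2])
    for (tr in trackset$tracks) {
      for (e in tr$entries) {
        if (e$frame_index == fidx &&
            (include_carried || e$status != "carried")) {
          m[e$mask$idx] <- tr$track_id
        }
      }
    }
    label_frame(m, frame_index = fidx)
  })
  out
}
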