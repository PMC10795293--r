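#' Extract per-leaf trait time series from a track set
#'
#' Applies each track entry's mask to the trait parameter image of the
#' same frame and records the mean pixel value — the per-leaf trait at
#' that timepoint. Carried entries (missed detections holding a stale
#' mask) are emitted too, flagged by their status, so downstream analysis
#' can filter them out; masked pixel means over a stale mask measure the
#' wrong region once the plant has grown.
#'
#' @param trackset A `track_set`.
#' @param trait_stack List of [trait_image()] objects (or bare matrices),
#'   one per frame, aligned to the mask grid.
#' @param trait_name Overrides the trait name recorded in the stack.
#' @return A tibble of class `leaf_trait_series`: `plant_id, track_id,
#'   frame_index, trait_name, status, area, mean_value`. Track id is leaf
#'   order (order of emergence and detection over time).
#' @export
extract_leaf_traits <- function(trackset, trait_stack, trait_name = NULL) {
  stopifnot(inherits(trackset, "track_set"))
  if (!length(trait_stack)) {
    stop("`trait_stack` is empty", call. = FALSE)
  }
  if (length(trait_stack) < trackset$n_frames) {
    stop("`trait_stack` holds fewer frames than the track set", call. = FALSE)
  }
  mats <- lapply(trait_stack, function(ti) {
    if (inherits(ti, "trait_image")) ti$values else ti
  })
  if (is.null(trait_name)) {
    trait_name <- if (inherits(trait_stack[[1]], "trait_image")) {
      trait_stack[[1]]$trait_name
    } else "trait"
  }
  rows <- purrr::map_dfr(trackset$tracks, function(tr) {
    purrr::map_dfr(tr$entries, function(e) {
      m <- mats[[e$frame_index + 1L]]
      if (!identical(as.integer(dim(m)), as.integer(e$mask$dim))) {
        stop("trait image shape does not match the mask grid at frame ",
             e$frame_index, call. = FALSE)
      }
      tibble::tibble(
        plant_id = trackset$plant_id,
        track_id = tr$track_id,
        frame_index = e$frame_index,
        trait_name = trait_name,
        status = e$status,
        area = mask_area(e$mask),
        mean_value = mean(m[e$mask$idx]))
    })
  })
  rows <- dplyr::arrange(rows, .data$track_id, .data$frame_index)
  class(rows) <- c("leaf_trait_series", class(rows))
  rows
}

#' Per-frame leaf counts of a track set
#'
#' Counts the tracks with an observed (non-carried) entry at each frame —
#' a summary of the number of instances tracked at each timepoint, used as
#' a developmental-progression readout.
#'
#' @param trackset A `track_set`.
#' @return A tibble `plant_id, frame_index, n_leaves` covering every frame
#'   (zero where nothing was observed).
#' @export
leaf_count_series <- function(trackset) {
  stopifnot(inherits(trackset, "track_set"))
  counts <- integer(trackset$n_frames)
  for (tr in trackset$tracks) {
    for (e in tr$entries) {
      if (e$status != "carried") {
        counts[e$frame_index + 1L] <- counts[e$frame_index + 1L] + 1L
      }
    }
  }
  tibble::tibble(plant_id = trackset$plant_id,
                 frame_index = seq_len(trackset$n_frames) - 1L,
                 n_leaves = counts)
}

#' Per-frame whole-plant trait means
#'
#' Mean trait value over the union of all instance masks of each frame
#' (each pixel counted once even where masks overlap) — the plant-level
#' counterpart of [extract_leaf_traits()].
#'
#' @param frames List with one element per timepoint, each a list of
#'   [instance_mask()] objects.
#' @param trait_stack List of [trait_image()] objects or matrices, one per
#'   frame.
#' @param trait_name,plant_id Metadata for the output.
#' @return A tibble `plant_id, frame_index, trait_name, area, mean_value`;
#'   frames with no masks get `NA` mean and zero area.
#' @export
plant_mean_series <- function(frames, trait_stack, trait_name = "trait",
                              plant_id = 1L) {
  if (length(trait_stack) < length(frames)) {
    stop("`trait_stack` holds fewer frames than `frames`", call. = FALSE)
  }
  mats <- lapply(trait_stack, function(ti) {
    if (inherits(ti, "trait_image")) ti$values else ti
  })
  purrr::map_dfr(seq_along(frames), function(f) {
    idx <- sort(unique(unlist(lapply(frames[[f]], `[[`, "idx"))))
    tibble::tibble(
      plant_id = plant_id,
      frame_index = f - 1L,
      trait_name = trait_name,
      area = length(idx),
      mean_value = if (length(idx)) mean(mats[[f]][idx]) else NA_real_)
  })
}

#' Per-timepoint two-group comparison
#'
#' Welch's two-sample t-test at every frame between two groups of
#' per-plant values (leaf counts or trait means), the standard screen for
#' genotype differences over a phenotyping time course. Pooled-variance
#' (Student) form is available via `var_equal = TRUE`. Frames with fewer
#' than two replicates in either group are skipped with a warning. When
#' both groups are constant: equal means give t = 0, p = 1; different
#' means give infinite t, p = 0 — both flagged. P-values are reported
#' unadjusted by default (`p_adjust = "none"`); `"BH"` applies
#' Benjamini-Hochberg across frames.
#'
#' @param series_a,series_b Tibbles with at least `frame_index` and a value
#'   column (plus one row per plant replicate).
#' @param value Name of the value column, default `"value"` (falls back to
#'   `"mean_value"` or `"n_leaves"` if present).
#' @param var_equal Use pooled variance instead of Welch, default `FALSE`.
#' @param p_adjust Multiple-testing correction across frames, `"none"`
#'   (default) or any [stats::p.adjust()] method.
#' @return A tibble of class `leaf_group_comparison`: `frame_index, n_a,
#'   n_b, mean_a, mean_b, t, p, flag`.
#' @export
group_compare <- function(series_a, series_b, value = NULL,
                          var_equal = FALSE, p_adjust = "none") {
  pick_col <- function(df) {
    if (!is.null(value)) return(value)
    for (cand in c("value", "mean_value", "n_leaves")) {
      if (cand %in% names(df)) return(cand)
    }
    stop("cannot find a value column; pass `value`", call. = FALSE)
  }
  col_a <- pick_col(series_a); col_b <- pick_col(series_b)
  frames <- sort(union(series_a$frame_index, series_b$frame_index))
  skipped <- integer(0)
  out <- purrr::map_dfr(frames, function(f) {
    xa <- series_a[[col_a]][series_a$frame_index == f]
    xb <- series_b[[col_b]][series_b$frame_index == f]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      skipped <<- c(skipped, f)
      return(tibble::tibble(frame_index = f, n_a = length(xa), n_b = length(xb),
                            mean_a = mean(xa), mean_b = mean(xb),
                            t = NA_real_, p = NA_real_,
                            flag = "skipped: <2 replicates"))
    }
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      if (mean(xa) == mean(xb)) {
        return(tibble::tibble(frame_index = f, n_a = length(xa), n_b = length(xb),
                              mean_a = mean(xa), mean_b = mean(xb),
                              t = 0, p = 1, flag = "zero variance, equal means"))
      }
      return(tibble::tibble(frame_index = f, n_a = length(xa), n_b = length(xb),
                            mean_a = mean(xa), mean_b = mean(xb),
                            t = sign(mean(xa) - mean(xb)) * Inf, p = 0,
                            flag = "zero variance, different means"))
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    tibble::tibble(frame_index = f, n_a = length(xa), n_b = length(xb),
                   mean_a = mean(xa), mean_b = mean(xb),
                   t = unname(tt$statistic), p = tt$p.value, flag = NA_character_)
  })
  if (length(skipped)) {
    warning("skipped frames with <2 replicates: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (p_adjust != "none") {
    out$p <- stats::p.adjust(out$p, method = p_adjust)
  }
  class(out) <- c("leaf_group_comparison", class(out))
  out
}
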