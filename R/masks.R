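#' Create an instance mask
#'
#' An instance mask is one leaf's binary footprint on a fixed-size image
#' grid, stored as a sorted set of linear pixel indices (column-major, as in
#' base R matrices). Coordinates follow the raster convention: 0-based
#' `(row, col)` with row 0 at the image top.
#'
#' @param pixels Either a logical/numeric matrix (non-zero = mask) or an
#'   integer vector of 1-based linear indices into a matrix of dimension
#'   `dim`.
#' @param dim Image dimensions `c(height, width)`; required when `pixels`
#'   is an index vector, inferred when it is a matrix.
#' @param confidence Detection confidence in `[0, 1]`, or `NA` for ground
#'   truth masks.
#' @param frame_index 0-based timepoint of the mask.
#' @param local_id Positive integer identifying the mask within its frame
#'   (the label value for label-image input, the annotation order for
#'   polygon input).
#'
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(pixels, dim = NULL, confidence = NA_real_,
                          frame_index = 0L, local_id = 1L) {
  if (is.matrix(pixels)) {
    dim <- base::dim(pixels)
    idx <- which(pixels != 0)
  } else {
    if (is.null(dim)) {
      stop("`dim` must be given when `pixels` is an index vector", call. = FALSE)
    }
    idx <- sort(unique(as.integer(pixels)))
    if (length(idx) && (idx[1] < 1L || idx[length(idx)] > prod(dim))) {
      stop("pixel indices fall outside the declared image dimensions",
           call. = FALSE)
    }
  }
  if (!is.na(confidence) && (confidence < 0 || confidence > 1)) {
    stop("`confidence` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(idx = as.integer(idx), dim = as.integer(dim),
         confidence = as.double(confidence),
         frame_index = as.integer(frame_index),
         local_id = as.integer(local_id)),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> frame %d, id %d, area %d px on %dx%d grid%s\n",
              x$frame_index, x$local_id, mask_area(x), x$dim[1], x$dim[2],
              if (is.na(x$confidence)) "" else
                sprintf(", confidence %.3f", x$confidence)))
  invisible(x)
}

#' Mask area in pixels
#' @param mask An `instance_mask`.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) length(mask$idx)

#' Mask centroid
#' @param mask An `instance_mask`.
#' @return Named numeric vector `c(row, col)` in 0-based coordinates.
#' @export
mask_centroid <- function(mask) {
  if (!length(mask$idx)) return(c(row = NA_real_, col = NA_real_))
  rc <- arrayInd(mask$idx, mask$dim)
  c(row = mean(rc[, 1]) - 1, col = mean(rc[, 2]) - 1)
}

#' Render a mask as a logical matrix
#' @param mask An `instance_mask`.
#' @return Logical matrix of the mask's image dimensions.
#' @export
mask_matrix <- function(mask) {
  m <- matrix(FALSE, mask$dim[1], mask$dim[2])
  m[mask$idx] <- TRUE
  m
}

#' Create a label frame
#'
#' A label frame is one timepoint's full instance segmentation: an integer
#' image where 0 is background and each positive value is one instance.
#' Labels need not be consecutive and are never re-mapped.
#'
#' @param labels Integer matrix, non-negative.
#' @param frame_index 0-based timepoint.
#' @return An object of class `label_frame`.
#' @export
label_frame <- function(labels, frame_index = 0L) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (anyNA(labels) || any(labels < 0)) {
    stop("label images must be non-negative integers", call. = FALSE)
  }
  if (any(labels != round(labels))) {
    stop("label images must contain integer values", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, frame_index = as.integer(frame_index),
                 dim = dim(labels)),
            class = "label_frame")
}

#' @export
print.label_frame <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<label_frame> frame %d, %dx%d, %d instance(s)\n",
              x$frame_index, x$dim[1], x$dim[2], length(labs)))
  invisible(x)
}

#' Split a label frame into instance masks
#'
#' Returns one `instance_mask` per positive label, ordered by ascending
#' label value; the union of the returned pixel sets is exactly the set of
#' non-background pixels. Ground-truth masks carry no confidence.
#'
#' @param frame A `label_frame`.
#' @return List of `instance_mask` objects (empty for an all-background frame).
#' @export
masks_from_labels <- function(frame) {
  stopifnot(inherits(frame, "label_frame"))
  labs <- setdiff(sort(unique(as.vector(frame$labels))), 0L)
  lapply(labs, function(l) {
    instance_mask(which(frame$labels == l), dim = frame$dim,
                  frame_index = frame$frame_index, local_id = l)
  })
}

#' Intersection over union of two masks
#'
#' IoU(A, B) = |A intersect B| / |A union B|, the similarity measure used
#' both for frame-to-frame association and for scoring predicted against
#' ground-truth segmentations.
#'
#' @param a,b `instance_mask` objects on the same image grid.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(a, b) {
  if (!identical(a$dim, b$dim)) {
    stop("masks live on different image grids", call. = FALSE)
  }
  na <- length(a$idx); nb <- length(b$idx)
  if (na == 0L && nb == 0L) {
    stop("IoU of two empty masks is undefined", call. = FALSE)
  }
  i <- length(intersect(a$idx, b$idx))
  i / (na + nb - i)
}

#' Pairwise IoU matrix between two mask lists
#'
#' @param queries,targets Lists of `instance_mask` objects on one grid.
#' @return Numeric matrix of dimension `length(queries)` x `length(targets)`
#'   with entry `(i, j) = compute_iou(queries[[i]], targets[[j]])`.
#' @export
iou_matrix <- function(queries, targets) {
  nq <- length(queries); nt <- length(targets)
  m <- matrix(0, nq, nt)
  if (nq == 0L || nt == 0L) return(m)
  for (i in seq_len(nq)) {
    qi <- queries[[i]]$idx
    for (j in seq_len(nt)) {
      tj <- targets[[j]]$idx
      inter <- length(intersect(qi, tj))
      m[i, j] <- inter / (length(qi) + length(tj) - inter)
    }
  }
  m
}
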