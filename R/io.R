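#' Read a label image from PNG or TIFF
#'
#' Label images are single-channel 8- or 16-bit images where pixel value 0
#' is background and each positive value is one instance. Values are
#' preserved exactly; the reader never relabels, so stable ground-truth
#' track identities survive a round trip.
#'
#' @param path Path to a single-channel PNG or TIFF file.
#' @param frame_index 0-based timepoint to record on the frame.
#' @return A [label_frame()].
#' @export
read_label_frame <- function(path, frame_index = 0L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2L) {
      stop("label PNG must be single-channel: ", path, call. = FALSE)
    }
    depth <- png_bit_depth(path)
    labels <- round(img * (2^depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) {
      stop("label TIFF must be single-channel: ", path, call. = FALSE)
    }
    labels <- img
  } else {
    stop("unsupported label image format: .", ext, call. = FALSE)
  }
  label_frame(matrix(as.integer(labels), nrow(labels), ncol(labels)),
              frame_index = frame_index)
}

# PNG stores bit depth in byte 25 of the file (IHDR chunk).
png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 26L)
  depth <- as.integer(hdr[25])
  if (!depth %in% c(1L, 2L, 4L, 8L, 16L)) {
    stop("cannot determine PNG bit depth for ", path, call. = FALSE)
  }
  depth
}

#' Write a label image
#'
#' PNG output is 8-bit (labels must be below 256); TIFF output is 16-bit
#' and round-trips any label up to 65535 exactly.
#'
#' @param frame A [label_frame()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_frame <- function(frame, path) {
  stopifnot(inherits(frame, "label_frame"))
  ext <- tolower(tools::file_ext(path))
  mx <- max(frame$labels)
  if (ext == "png") {
    if (mx > 255L) {
      stop("labels exceed 255; write a 16-bit TIFF instead", call. = FALSE)
    }
    png::writePNG(frame$labels / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (mx > 65535L) stop("labels exceed 65535", call. = FALSE)
    tiff::writeTIFF(frame$labels / 65535, path, bits.per.sample = 16L)
  } else {
    stop("unsupported label image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a trait parameter image
#'
#' Accepts single-channel TIFF (including float), PNG, or a plain-text CSV
#' numeric matrix without header.
#'
#' @param path Input path.
#' @param trait_name,frame_index Metadata recorded on the result.
#' @param normalize If `TRUE`, min-max normalize to `[0, 1]`.
#' @return A [trait_image()].
#' @export
read_trait_image <- function(path, trait_name = "trait", frame_index = 0L,
                             normalize = FALSE) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("csv", "txt")) {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    stop("unsupported trait image format: .", ext, call. = FALSE)
  }
  if (length(dim(vals)) != 2L) {
    stop("trait image must be single-channel: ", path, call. = FALSE)
  }
  vals <- matrix(as.double(vals), nrow(vals), ncol(vals))
  trait_image(vals, trait_name = trait_name, frame_index = frame_index,
              normalize = normalize)
}

#' Read detector output from a COCO-style annotation file
#'
#' Ingests the standard instance-segmentation interchange format: a JSON
#' object with an `images` array (`id`, `height`, `width`) and an
#' `annotations` array whose `segmentation` is either a list of polygons
#' (flat `x1,y1,x2,y2,...` vertex lists) or an uncompressed run-length
#' encoding (`{size: [h, w], counts: [...]}`, column-major, starting with a
#' background run). A `score` field, when present, is stored as the mask's
#' detection confidence.
#'
#' Polygons are rasterized with the pixel-center rule: a 0-based pixel
#' `(row, col)` belongs to the mask when its center `(x = col, y = row)`
#' lies inside or on the polygon boundary.
#'
#' Frames are ordered by ascending image `id` and assigned 0-based frame
#' indices in that order (or taken from an optional per-image `frame_index`
#' field). Within a frame, annotation input order is preserved.
#'
#' @param path Path to the JSON file.
#' @return A list with one element per frame, each a list of
#'   [instance_mask()] objects (possibly empty). An empty annotation file
#'   yields an empty list.
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  images <- doc$images %||% list()
  anns <- doc$annotations %||% list()
  if (!length(images)) return(list())

  ids <- vapply(images, function(im) as.integer(im$id), integer(1))
  ord <- order(ids)
  images <- images[ord]
  frames <- lapply(seq_along(images), function(k) {
    im <- images[[k]]
    if (is.null(im$height) || is.null(im$width)) {
      stop("image entry missing height/width: id ", im$id, call. = FALSE)
    }
    fidx <- if (!is.null(im$frame_index)) as.integer(im$frame_index) else k - 1L
    list(id = as.integer(im$id), dim = c(as.integer(im$height),
                                         as.integer(im$width)),
         frame_index = fidx, masks = list())
  })
  names(frames) <- as.character(vapply(frames, `[[`, integer(1), "id"))

  for (ann in anns) {
    key <- as.character(as.integer(ann$image_id))
    fr <- frames[[key]]
    if (is.null(fr)) {
      stop("annotation references unknown image_id ", ann$image_id,
           call. = FALSE)
    }
    conf <- NA_real_
    if (!is.null(ann$score)) {
      conf <- as.double(ann$score)
      if (is.na(conf) || conf < 0 || conf > 1) {
        stop("annotation score outside [0, 1]: ", ann$score, call. = FALSE)
      }
    }
    idx <- segmentation_to_indices(ann$segmentation, fr$dim)
    fr$masks[[length(fr$masks) + 1L]] <-
      instance_mask(idx, dim = fr$dim, confidence = conf,
                    frame_index = fr$frame_index,
                    local_id = length(fr$masks) + 1L)
    frames[[key]] <- fr
  }
  lapply(unname(frames), `[[`, "masks")
}

segmentation_to_indices <- function(seg, dim) {
  if (is.null(seg)) stop("annotation has no segmentation", call. = FALSE)
  if (!is.null(seg$counts)) {
    return(rle_to_indices(seg, dim))
  }
  idx <- integer(0)
  for (poly in seg) {
    v <- as.double(unlist(poly))
    if (length(v) < 6L || length(v) %% 2L != 0L) {
      stop("polygon must hold >= 3 (x, y) vertex pairs", call. = FALSE)
    }
    xs <- v[seq(1, length(v), by = 2)]
    ys <- v[seq(2, length(v), by = 2)]
    idx <- union(idx, rasterize_polygon(xs, ys, dim))
  }
  sort(idx)
}

# Pixel-center-in-polygon rasterization on the 0-based grid; boundary
# pixels are included.
rasterize_polygon <- function(xs, ys, dim) {
  h <- dim[1]; w <- dim[2]
  r0 <- max(0, floor(min(ys))); r1 <- min(h - 1, ceiling(max(ys)))
  c0 <- max(0, floor(min(xs))); c1 <- min(w - 1, ceiling(max(xs)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1
  cols <- c0:c1
  grid <- expand.grid(row = rows, col = cols)
  inside <- pracma::inpolygon(grid$col, grid$row, xs, ys, boundary = TRUE)
  rc <- grid[inside, , drop = FALSE]
  as.integer(rc$row + 1L + rc$col * h)
}

# Uncompressed COCO RLE: column-major runs alternating background /
# foreground, starting with background.
rle_to_indices <- function(seg, dim) {
  size <- as.integer(unlist(seg$size))
  if (!identical(size, as.integer(dim))) {
    stop("RLE size does not match image dimensions", call. = FALSE)
  }
  counts <- as.integer(unlist(seg$counts))
  if (sum(counts) != prod(dim)) {
    stop("RLE counts do not cover the image", call. = FALSE)
  }
  ends <- cumsum(counts)
  starts <- c(1L, ends[-length(ends)] + 1L)
  fg <- seq_along(counts) %% 2L == 0L & counts > 0L
  idx <- unlist(Map(seq.int, starts[fg], ends[fg]), use.names = FALSE)
  as.integer(idx)
}

#' Write a track table to CSV
#'
#' Long-format export of a [track_sequence()] result: one row per track
#' entry with columns `plant_id, track_id, frame_index, status, area,
#' centroid_row, centroid_col`, ordered by track then frame.
#'
#' @param trackset A `track_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(trackset, path) {
  tab <- track_table(trackset)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
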