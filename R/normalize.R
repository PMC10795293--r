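#' Min-max normalize a trait data matrix
#'
#' Chlorophyll-fluorescence phenotyping systems export parameter images
#' (Fv/Fm, PhiPSII) as raw numeric matrices; downstream analysis uses them
#' rescaled to `[0, 1]` as `(x - min) / (max - min)`. A constant matrix
#' (max = min) maps to all zeros, the conservative "no signal" convention.
#'
#' @param raw Finite numeric matrix.
#' @return Matrix of the same dimensions with values in `[0, 1]`.
#' @export
normalize_matrix <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(raw) || any(!is.finite(raw))) {
    stop("`raw` contains NA/NaN/Inf entries", call. = FALSE)
  }
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    return(matrix(0, nrow(raw), ncol(raw)))
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Create a trait parameter image
#'
#' @param values Numeric matrix of per-pixel trait values, aligned to the
#'   segmentation grid of the same frame.
#' @param trait_name Trait label, e.g. `"FvFm"` or `"PhiPSII"`.
#' @param frame_index 0-based timepoint.
#' @param normalize If `TRUE`, pass `values` through [normalize_matrix()].
#' @return An object of class `trait_image`.
#' @export
trait_image <- function(values, trait_name = "trait", frame_index = 0L,
                        normalize = FALSE) {
  if (normalize) values <- normalize_matrix(values)
  structure(list(values = values, trait_name = trait_name,
                 frame_index = as.integer(frame_index), dim = dim(values)),
            class = "trait_image")
}
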