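#' @useDynLib tumorpatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Validate a grayscale image matrix
#'
#' A grayscale image is a plain numeric matrix with all values in
#' \eqn{[0, 1]}. Matrix indices follow R's 1-based (row, col) convention;
#' serialized reports use 0-based coordinates (see [write_report()]).
#'
#' @param img object to check.
#' @param arg name used in error messages.
#' @return `img`, invisibly.
#' @keywords internal
assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(arg, " must have at least one row and one column", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop(arg, " intensities must be finite and lie in [0, 1]", call. = FALSE)
  invisible(img)
}

#' @rdname assert_gray_image
#' @param mask object to check.
#' @param shape optional required dim.
#' @keywords internal
assert_mask <- function(mask, arg = "mask", shape = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(arg, " must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop(arg, " must not contain NA", call. = FALSE)
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape)))
    stop(arg, " shape does not match the image it annotates", call. = FALSE)
  invisible(mask)
}

#' Min-max normalize a numeric array to [0, 1]
#'
#' A constant input (zero range) maps to all zeros.
#'
#' @param x numeric matrix or array.
#' @return numeric matrix in \eqn{[0, 1]}.
#' @export
normalize_minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(array(0, dim = dim(x)))
  (x - rng[1]) / diff(rng)
}

rgb_to_luminance <- function(arr) {
  # Rec. 601 luma weights, as used by common grayscale conversions
  w <- c(0.299, 0.587, 0.114)
  nch <- dim(arr)[3]
  if (nch >= 3) {
    arr[, , 1] * w[1] + arr[, , 2] * w[2] + arr[, , 3] * w[3]
  } else {
    arr[, , 1]
  }
}

#' Load a 2-D grayscale brain MRI slice
#'
#' Reads PNG, TIFF (8/16-bit) or NIfTI (`.nii` / `.nii.gz`) images and
#' returns a min-max normalized grayscale matrix. Multichannel images are
#' converted to luminance before normalization. For 3-D NIfTI volumes,
#' `slice_index` selects one axial slice (third array index, 1-based).
#'
#' @param path path to a PNG, TIFF or NIfTI file.
#' @param slice_index 1-based axial slice for 3-D NIfTI volumes. Ignored for
#'   2-D inputs.
#' @return numeric matrix in \eqn{[0, 1]} with (row, col) orientation.
#' @export
load_image <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    arr <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    arr <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3L) {
      if (is.null(slice_index))
        stop("slice_index is required for a 3-D NIfTI volume", call. = FALSE)
      if (slice_index < 1L || slice_index > dim(arr)[3])
        stop("slice_index out of range: ", slice_index, call. = FALSE)
      arr <- arr[, , slice_index]
    } else if (length(dim(arr)) != 2L) {
      stop("unsupported NIfTI dimensionality", call. = FALSE)
    }
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) arr <- rgb_to_luminance(arr)
  img <- normalize_minmax(arr)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  assert_gray_image(img)
  img
}

#' Linear contrast stretch (window and clip)
#'
#' Maps the intensity window `[lo, hi]` linearly onto `[0, 1]` and clips
#' everything outside: `clip((x - lo) / (hi - lo), 0, 1)`. A very narrow
#' window such as (0.4999, 0.5001) acts as a near-binarization at
#' mid-intensity and is used to focus the detector on bright (abnormal)
#' tissue.
#'
#' @param img grayscale matrix in \eqn{[0, 1]}.
#' @param lo lower window edge in `[0, 1)`.
#' @param hi upper window edge in `(lo, 1]`.
#' @return stretched image, same shape, values in \eqn{[0, 1]}.
#' @export
contrast_stretch <- function(img, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || lo >= hi)
    stop("contrast window requires lo < hi", call. = FALSE)
  assert_gray_image(img)
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @return `read_mask` returns a logical matrix.
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr >= 0.5
}
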