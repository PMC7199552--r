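#' Preprocessing configuration
#'
#' Parameters of the two "modified images" whose product is the detection
#' input: a small box-mean filter (noise removal), a very narrow intensity
#' window centered at 50% (49.99-50.01%, a near-binarization that keeps
#' only pixels brighter than mid-intensity, i.e. abnormal tissue), and a
#' wide 10-90% window that re-expands contrast on what remains.
#'
#' @param avg_kernel_size odd box-filter size in pixels.
#' @param narrow_window length-2 numeric `(lo, hi)` in `[0, 1]`.
#' @param wide_window length-2 numeric `(lo, hi)` in `[0, 1]`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(avg_kernel_size = 3L,
                              narrow_window = c(0.4999, 0.5001),
                              wide_window = c(0.10, 0.90)) {
  avg_kernel_size <- as.integer(avg_kernel_size)
  if (avg_kernel_size < 1L || avg_kernel_size %% 2L == 0L)
    stop("avg_kernel_size must be odd and >= 1", call. = FALSE)
  for (w in list(narrow_window, wide_window))
    if (length(w) != 2L || w[1] >= w[2])
      stop("windows must satisfy lo < hi", call. = FALSE)
  structure(list(avg_kernel_size = avg_kernel_size,
                 narrow_window = as.numeric(narrow_window),
                 wide_window = as.numeric(wide_window)),
            class = "preprocess_config")
}

#' Cerebral tissue mask
#'
#' Removes the inward skull band from the medium-intensity cluster, keeps
#' the largest 8-connected component (the cerebrum) and fills its holes
#' (bright tumors punch holes in the medium cluster and must be covered by
#' the mask).
#'
#' @param medium logical medium-cluster mask.
#' @param inward_band logical band from [expand_edge_inward()].
#' @return logical matrix.
#' @export
cerebral_mask <- function(medium, inward_band) {
  assert_mask(medium, "medium")
  assert_mask(inward_band, "inward_band", shape = dim(medium))
  m <- medium & !inward_band
  if (!any(m))
    stop("no cerebral tissue found after removing the skull band",
         call. = FALSE)
  fill_holes(largest_component(m))
}

#' Contrast-focused image
#'
#' `box_mean(img) * contrast_stretch(img, narrow)` followed by a wide
#' contrast stretch: the mean filter suppresses speckle while the narrow
#' mid-intensity window keeps only pixels brighter than 50%, concentrating
#' the result on abnormal (bright) tissue.
#'
#' @param img grayscale matrix in \eqn{[0, 1]}.
#' @param cfg a [preprocess_config()].
#' @return grayscale matrix in \eqn{[0, 1]}.
#' @export
focus_image <- function(img, cfg = preprocess_config()) {
  assert_gray_image(img)
  filtered <- box_mean(img, cfg$avg_kernel_size)
  narrow <- contrast_stretch(img, cfg$narrow_window[1], cfg$narrow_window[2])
  contrast_stretch(filtered * narrow, cfg$wide_window[1], cfg$wide_window[2])
}

#' Detection input image
#'
#' Element-wise product of the cerebral mask (as 0/1) with the
#' contrast-focused image: bright structures outside the cerebrum (skull,
#' scalp, skull-attached decoys) are zeroed while interior tumors are
#' retained.
#'
#' @param img grayscale matrix.
#' @param cereb logical cerebral mask from [cerebral_mask()].
#' @param cfg a [preprocess_config()].
#' @return grayscale matrix in \eqn{[0, 1]} supported inside `cereb`.
#' @export
modified_image <- function(img, cereb, cfg = preprocess_config()) {
  assert_gray_image(img)
  assert_mask(cereb, "cereb", shape = dim(img))
  (cereb * 1) * focus_image(img, cfg)
}
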