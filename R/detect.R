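#' Per-patch detection parameters
#'
#' @param thresholds fixed binarization thresholds in (0, 1); a per-patch
#'   Otsu threshold is appended when `use_otsu` is `TRUE` and the patch is
#'   not constant.
#' @param use_otsu append the per-patch Otsu threshold?
#' @param min_object_area smallest object (pixels, at working scale) kept in
#'   each binary image. The default of 100 sits just below the working-scale
#'   footprint of the smallest targeted tumor (radius 2 px at the default
#'   3x upscale covers about 117 px) and above the blob a single noise pixel
#'   spreads to (about 30-50 px), so noise is eliminated while every real
#'   tumor survives; at native scale the same cutoff swallows small tumors,
#'   which is precisely why patches are upscaled before detection.
#' @param grow_delta region-growing intensity tolerance: the flood accepts
#'   pixels at least `seed intensity - grow_delta` bright.
#' @param contrast_pass_window `(lo, hi)` window of the second detection
#'   pass (30-70% contrast boost).
#' @param max_candidates cap on candidate-elimination iterations per pass.
#' @param low_intensity_cutoff intensities below this are zeroed before
#'   thresholding (background speckle removal).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(thresholds = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             use_otsu = TRUE,
                             min_object_area = 100L,
                             grow_delta = 0.2,
                             contrast_pass_window = c(0.30, 0.70),
                             max_candidates = 20L,
                             low_intensity_cutoff = 0.05) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (min_object_area < 1L) stop("min_object_area must be >= 1", call. = FALSE)
  if (grow_delta <= 0 || grow_delta >= 1)
    stop("grow_delta must lie in (0, 1)", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 use_otsu = isTRUE(use_otsu),
                 min_object_area = as.integer(min_object_area),
                 grow_delta = grow_delta,
                 contrast_pass_window = as.numeric(contrast_pass_window),
                 max_candidates = as.integer(max_candidates),
                 low_intensity_cutoff = low_intensity_cutoff),
            class = "detection_params")
}

#' Otsu's threshold over a 256-bin histogram
#'
#' Returns the cut maximizing between-class variance; a constant patch has
#' no meaningful cut and yields `NA`, which callers treat as "skip the Otsu
#' binarization".
#'
#' @param patch grayscale matrix in \eqn{[0, 1]}.
#' @return threshold in (0, 1), or `NA_real_` for a constant patch.
#' @export
otsu_threshold <- function(patch) {
  assert_gray_image(patch)
  if (min(patch) == max(patch)) return(NA_real_)
  EBImage::otsu(patch, range = c(0, 1), levels = 256L)
}

#' Erode a mask with growing disks until one object remains
#'
#' For r = 0, 1, 2, ... the original mask is eroded with the discrete disk
#' of radius r; the first r leaving exactly one 8-connected component wins.
#' If a step jumps from two or more components to zero, the largest
#' component of the last non-empty erosion is returned together with the
#' radius of the jump (ties broken by area, then topmost-leftmost centroid).
#'
#' @param mask logical matrix with at least one true pixel.
#' @return list with `survivor` (logical matrix) and `radius` (integer).
#' @export
erode_until_single <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("cannot erode an empty mask", call. = FALSE)
  prev <- mask
  r_max <- ceiling(max(dim(mask)) / 2) + 1L
  for (r in 0:r_max) {
    er <- if (r == 0L) mask else binary_erode(mask, disk_kernel(r))
    n <- count_objects(er)
    if (n == 1L) return(list(survivor = er, radius = r))
    if (n == 0L)
      return(list(survivor = largest_component(prev), radius = r))
    prev <- er
  }
  list(survivor = largest_component(prev), radius = r_max)
}

#' Seeded region growing
#'
#' 8-connected flood from the seed over pixels whose intensity is at least
#' `intensity(seed) - delta`, bounded by the image. An optional `floor`
#' keeps the acceptance level from sinking into the background: the flood
#' never admits pixels below it, so a dim seed cannot engulf the whole
#' image (the detector uses its low-intensity cutoff here).
#'
#' @param img grayscale matrix.
#' @param seed integer `(row, col)`, 1-based, inside the image.
#' @param delta homogeneity tolerance in intensity units.
#' @param floor lower bound on the acceptance level (default 0, i.e. none).
#' @return logical matrix containing the grown region (always includes the
#'   seed).
#' @export
region_grow <- function(img, seed, delta, floor = 0) {
  assert_gray_image(img)
  seed <- as.integer(seed)
  if (seed[1] < 1L || seed[1] > nrow(img) ||
      seed[2] < 1L || seed[2] > ncol(img))
    stop("seed out of bounds", call. = FALSE)
  level <- max(img[seed[1], seed[2]] - delta, floor)
  eligible <- img >= level
  eligible[seed[1], seed[2]] <- TRUE  # the seed always belongs
  lab <- label_components(eligible, 8L)
  lab == lab[seed[1], seed[2]]
}

# One detection pass over a working-scale patch: low-intensity elimination,
# smoothing, multi-threshold binarization with small-object removal and hole
# filling, accumulation, then iterative candidate extraction (max-vote
# component -> erode to one object -> region growing -> eliminate).
detect_pass <- function(patch, params) {
  shape <- dim(patch)
  cand <- matrix(FALSE, shape[1], shape[2])
  patch[patch < params$low_intensity_cutoff] <- 0
  if (max(patch) == 0) return(cand)
  sm <- box_mean(patch, 3L)
  ths <- params$thresholds
  if (params$use_otsu) {
    ot <- otsu_threshold(sm)
    if (!is.na(ot)) ths <- c(ths, ot)
  }
  acc <- matrix(0L, shape[1], shape[2])
  for (t in ths) {
    b <- sm > t
    b <- remove_small_objects(b, params$min_object_area)
    b <- fill_holes(b)
    acc <- acc + b
  }
  for (iter in seq_len(params$max_candidates)) {
    if (!any(acc > 0L)) break
    lab <- label_components(acc > 0L, 8L)
    mx <- max(acc)
    best <- pick_component(lab, unique(lab[acc == mx]))
    comp <- lab == best
    surv <- erode_until_single(comp)$survivor
    seed <- survivor_seed(surv)
    grown <- region_grow(sm, seed, params$grow_delta,
                         floor = params$low_intensity_cutoff)
    cand <- cand | grown
    # the detected object is eliminated: both its grown extent and the
    # accumulation component it was found in (otherwise the component's
    # low-threshold skirt would be re-detected as a spurious halo)
    acc[grown | comp] <- 0L
  }
  cand
}

# Center of the surviving object, snapped to the nearest survivor pixel when
# the rounded centroid falls outside it (e.g. ring-shaped survivors).
survivor_seed <- function(surv) {
  idx <- which(surv)
  r <- ((idx - 1L) %% nrow(surv)) + 1L
  c_ <- ((idx - 1L) %/% nrow(surv)) + 1L
  seed <- c(round(mean(r)), round(mean(c_)))
  if (!surv[seed[1], seed[2]]) {
    d2 <- (r - seed[1])^2 + (c_ - seed[2])^2
    i <- which.min(d2)
    seed <- c(r[i], c_[i])
  }
  seed
}

#' Detect tumor candidates in one working-scale patch
#'
#' Runs two passes over the (already upscaled) patch: the raw patch and the
#' patch contrast-boosted through the 30-70% window. Each pass binarizes the
#' smoothed patch at every threshold, cleans and fills the binary images,
#' sums them into an accumulation image, and repeatedly extracts the
#' strongest candidate: the component holding the maximum accumulated vote
#' is eroded to a single object, a region is grown from its center, added to
#' the candidate mask and eliminated from the accumulation, until the
#' accumulation is empty or `max_candidates` is reached. The union of both
#' passes is returned.
#'
#' @param patch grayscale matrix at working scale.
#' @param params a [detection_params()].
#' @return logical candidate mask, same shape as `patch`.
#' @export
detect_in_patch <- function(patch, params = detection_params()) {
  assert_gray_image(patch)
  w <- params$contrast_pass_window
  detect_pass(patch, params) |
    detect_pass(contrast_stretch(patch, w[1], w[2]), params)
}
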