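#' Split an image into non-overlapping patches
#'
#' The grid starts `offset` pixels before the image origin (top/left
#' zero-padding) and the image is zero-padded on the right/bottom to a
#' multiple of `patch_size`, so the patches tile the padded image exactly.
#' Patch origins are recorded in original 1-based coordinates (the first
#' origin is `1 - offset` when shifted).
#'
#' @param img grayscale matrix.
#' @param patch_size square patch side in pixels.
#' @param offset integer `(row_shift, col_shift)` in `[0, patch_size)`.
#' @return list of class `patch_grid`: `patch_size`, `offset`,
#'   `image_shape`, `padded_shape`, `grid_dim`, `origins`, `patches`.
#' @export
split_patches <- function(img, patch_size, offset = c(0L, 0L)) {
  assert_gray_image(img)
  patch_size <- as.integer(patch_size)
  offset <- as.integer(offset)
  if (patch_size < 1L) stop("patch_size must be >= 1", call. = FALSE)
  if (any(offset < 0L) || any(offset >= patch_size))
    stop("offsets must lie in [0, patch_size)", call. = FALSE)
  shape <- dim(img)
  n_r <- ceiling((shape[1] + offset[1]) / patch_size)
  n_c <- ceiling((shape[2] + offset[2]) / patch_size)
  padded <- matrix(0, n_r * patch_size, n_c * patch_size)
  padded[offset[1] + seq_len(shape[1]), offset[2] + seq_len(shape[2])] <- img
  origins <- vector("list", n_r * n_c)
  patches <- vector("list", n_r * n_c)
  i <- 0L
  for (pc in seq_len(n_c)) {
    for (pr in seq_len(n_r)) {
      i <- i + 1L
      pad_r <- (pr - 1L) * patch_size
      pad_c <- (pc - 1L) * patch_size
      origins[[i]] <- c(pad_r + 1L - offset[1], pad_c + 1L - offset[2])
      patches[[i]] <- padded[pad_r + seq_len(patch_size),
                             pad_c + seq_len(patch_size), drop = FALSE]
    }
  }
  structure(
    list(patch_size = patch_size, offset = offset, image_shape = shape,
         padded_shape = c(n_r, n_c) * patch_size, grid_dim = c(n_r, n_c),
         origins = origins, patches = patches),
    class = "patch_grid"
  )
}

#' Stitch per-patch masks back into a full-image mask
#'
#' @param grid the `patch_grid` the masks came from.
#' @param masks list of logical matrices, one per patch, at patch scale.
#' @return logical matrix of `grid$image_shape`.
#' @export
stitch_masks <- function(grid, masks) {
  stopifnot(inherits(grid, "patch_grid"),
            length(masks) == length(grid$patches))
  canvas <- matrix(FALSE, grid$padded_shape[1], grid$padded_shape[2])
  ps <- grid$patch_size
  for (i in seq_along(masks)) {
    o <- grid$origins[[i]] + grid$offset - 1L  # padded coordinates
    canvas[o[1] + seq_len(ps), o[2] + seq_len(ps)] <- masks[[i]]
  }
  canvas[grid$offset[1] + seq_len(grid$image_shape[1]),
         grid$offset[2] + seq_len(grid$image_shape[2]), drop = FALSE]
}

#' Upscale a patch by bilinear interpolation
#'
#' Small tumors that cannot be resolved at the native image scale are
#' magnified three-fold before detection; `scale = 1` is the identity.
#'
#' @param patch grayscale matrix.
#' @param scale positive integer magnification.
#' @return grayscale matrix of `scale` times the input size.
#' @export
upscale <- function(patch, scale) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1", call. = FALSE)
  if (scale == 1L) return(patch)
  out <- EBImage::resize(patch, w = nrow(patch) * scale,
                         h = ncol(patch) * scale, filter = "bilinear")
  pmin(pmax(as_plain_matrix(out), 0), 1)
}

#' Downscale a working-scale mask by block majority
#'
#' Each `scale x scale` block maps to one output pixel, true when at least
#' half of the block is true.
#'
#' @param mask logical matrix of shape `scale * target_shape`.
#' @param scale positive integer reduction factor.
#' @param target_shape integer `(rows, cols)` of the output.
#' @return logical matrix of `target_shape`.
#' @export
downscale_mask <- function(mask, scale, target_shape) {
  assert_mask(mask)
  scale <- as.integer(scale)
  target_shape <- as.integer(target_shape)
  if (!identical(dim(mask), target_shape * scale))
    stop("mask shape is not scale * target_shape", call. = FALSE)
  if (scale == 1L) return(mask)
  g_r <- rep(seq_len(target_shape[1]), each = scale)
  sums <- rowsum(mask * 1L, g_r)
  g_c <- rep(seq_len(target_shape[2]), each = scale)
  sums <- t(rowsum(t(sums), g_c))
  dimnames(sums) <- NULL
  sums * 2L >= scale * scale
}

#' Run shifted patch-detection passes and accumulate votes
#'
#' For every shift, the image is split into patches, each patch is upscaled,
#' detected with [detect_in_patch()], the result reduced back to native
#' scale and stitched into a full-image mask; the vote map is the per-pixel
#' sum over shifts (one vote per shift). Patches entirely below the
#' low-intensity cutoff detect nothing and are skipped.
#'
#' @param img grayscale matrix (normally the modified detection image).
#' @param params a [detection_params()].
#' @param shifts list of `(row_shift, col_shift)` offsets.
#' @param patch_size patch side at native scale.
#' @param scale integer upscaling factor applied before detection.
#' @return list of class `vote_map`: `votes` (integer matrix), `n_passes`.
#' @export
run_passes <- function(img, params = detection_params(),
                       shifts = default_shifts(),
                       patch_size = 200L, scale = 3L) {
  assert_gray_image(img)
  if (!length(shifts)) stop("shifts must be nonempty", call. = FALSE)
  votes <- matrix(0L, nrow(img), ncol(img))
  for (sh in shifts) {
    grid <- split_patches(img, patch_size, sh)
    masks <- lapply(grid$patches, function(p) {
      if (max(p) < params$low_intensity_cutoff)
        return(matrix(FALSE, nrow(p), ncol(p)))
      det <- detect_in_patch(upscale(p, scale), params)
      downscale_mask(det, scale, dim(p))
    })
    votes <- votes + stitch_masks(grid, masks)
  }
  structure(list(votes = votes, n_passes = length(shifts)),
            class = "vote_map")
}

#' Default scanning shifts
#'
#' Four horizontal grid offsets 50 pixels apart, giving per-pixel votes
#' between zero and four.
#'
#' @param step shift increment in pixels.
#' @param n number of shifted grids.
#' @return list of `(row_shift, col_shift)` offsets.
#' @export
default_shifts <- function(step = 50L, n = 4L) {
  lapply(seq_len(n) - 1L, function(i) c(0L, i * step))
}

#' Pool two vote maps
#'
#' @param a,b `vote_map` objects over the same image.
#' @return combined `vote_map` with summed votes and passes.
#' @export
pool_votes <- function(a, b) {
  stopifnot(inherits(a, "vote_map"), inherits(b, "vote_map"),
            identical(dim(a$votes), dim(b$votes)))
  structure(list(votes = a$votes + b$votes,
                 n_passes = a$n_passes + b$n_passes),
            class = "vote_map")
}

#' Select pixels detected often enough
#'
#' Keeps pixels whose vote count reaches `min_votes`; with the default of 2
#' a region must be detected in at least two shifted passes to survive.
#'
#' @param vm a `vote_map`.
#' @param min_votes integer in `[1, n_passes]`.
#' @return logical matrix.
#' @export
select_candidates <- function(vm, min_votes = 2L) {
  stopifnot(inherits(vm, "vote_map"))
  min_votes <- as.integer(min_votes)
  if (min_votes < 1L || min_votes > vm$n_passes)
    stop("min_votes must lie in [1, n_passes]", call. = FALSE)
  vm$votes >= min_votes
}
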