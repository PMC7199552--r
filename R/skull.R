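#' Extract the largest surrounding edge (skull outline)
#'
#' The bright and medium k-means clusters are united, interior pixels (those
#' whose four axial neighbors are all set) are removed to leave an outline,
#' and the largest 8-connected outline component is returned. On a brain MRI
#' slice this is the skull boundary; it is retained (not stripped) and later
#' used to reject skull-adjacent false tumors.
#'
#' @param bright,medium logical cluster masks of identical shape.
#' @return logical matrix holding the largest outline component.
#' @export
largest_surrounding_edge <- function(bright, medium) {
  assert_mask(bright, "bright")
  assert_mask(medium, "medium", shape = dim(bright))
  u <- bright | medium
  if (!any(u)) stop("no brain found: bright and medium clusters are empty",
                    call. = FALSE)
  nr <- nrow(u); nc <- ncol(u)
  up <- rbind(FALSE, u[-nr, , drop = FALSE])
  dn <- rbind(u[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, u[, -nc, drop = FALSE])
  rt <- cbind(u[, -1, drop = FALSE], FALSE)
  interior <- u & up & dn & lf & rt
  outline <- u & !interior
  largest_component(outline)
}

#' Fill the skull edge and derive the brain-size-dependent threshold
#'
#' Holes inside the largest surrounding edge are filled by flood-filling the
#' border-connected background; the filled pixel count measures the brain
#' (cerebral tissue plus skull), and the Euclidean distance threshold used
#' for false-tumor rejection is mapped from that size with
#' [distance_threshold_from_size()]. An open (leaking) edge fills to itself;
#' this degenerate case is kept rather than guessed at.
#'
#' @param edge logical matrix, the largest surrounding edge.
#' @param anchors,min_threshold passed to [distance_threshold_from_size()].
#' @return object of class `skull_model`: `edge`, `filled`, `brain_pixels`,
#'   `distance_threshold`.
#' @export
fill_and_measure <- function(edge, anchors = default_distance_anchors(),
                             min_threshold = 3) {
  assert_mask(edge, "edge")
  if (!any(edge)) stop("edge mask is empty", call. = FALSE)
  filled <- fill_holes(edge)
  brain_pixels <- sum(filled)
  structure(
    list(edge = edge, filled = filled, brain_pixels = brain_pixels,
         distance_threshold = distance_threshold_from_size(
           brain_pixels, anchors, min_threshold)),
    class = "skull_model"
  )
}

#' Anchor points of the brain-size to distance-threshold mapping
#'
#' Small brains get small rejection distances (5 px at 5000 brain pixels,
#' 6 px at 8000) and large brains get large ones (25 px at 100000 pixels);
#' the threshold is directly proportional to brain size.
#'
#' @return two-column matrix `(brain_pixels, threshold)`.
#' @export
default_distance_anchors <- function() {
  cbind(size = c(5000, 8000, 100000), threshold = c(5, 6, 25))
}

#' Map brain size to the Euclidean distance threshold
#'
#' Piecewise-linear interpolation through the anchor points, with linear
#' extrapolation beyond the first/last segment and a floor of
#' `min_threshold` pixels.
#'
#' @param brain_pixels positive brain area in pixels (vectorized).
#' @param anchors two-column matrix `(size, threshold)`, ascending sizes.
#' @param min_threshold lower clamp for the returned threshold.
#' @return distance threshold(s) in pixels.
#' @export
distance_threshold_from_size <- function(brain_pixels,
                                         anchors = default_distance_anchors(),
                                         min_threshold = 3) {
  if (any(brain_pixels <= 0))
    stop("brain_pixels must be positive", call. = FALSE)
  sz <- anchors[, 1]; th <- anchors[, 2]
  if (is.unsorted(sz, strictly = TRUE))
    stop("anchor sizes must be strictly increasing", call. = FALSE)
  n <- length(sz)
  out <- vapply(brain_pixels, function(b) {
    if (b <= sz[1]) {
      th[1] + (b - sz[1]) * (th[2] - th[1]) / (sz[2] - sz[1])
    } else if (b >= sz[n]) {
      th[n] + (b - sz[n]) * (th[n] - th[n - 1]) / (sz[n] - sz[n - 1])
    } else {
      stats::approx(sz, th, xout = b)$y
    }
  }, numeric(1))
  pmax(out, min_threshold)
}

#' Expand the skull edge inward
#'
#' Returns the band `filled & !erode(filled, cross, iterations)`: a rim of
#' roughly `iterations` pixels just inside the skull boundary, produced by
#' iterated erosion with the 3x3 cross kernel. The band is removed from the
#' medium cluster when building the cerebral mask, so bright rims attached
#' to the skull cannot seed candidates.
#'
#' @param skull a `skull_model` from [fill_and_measure()].
#' @param iterations erosion count (band width); 0 gives an empty band.
#' @return logical matrix.
#' @export
expand_edge_inward <- function(skull, iterations = 10L) {
  stopifnot(inherits(skull, "skull_model"))
  if (iterations < 0L) stop("iterations must be >= 0", call. = FALSE)
  if (iterations == 0L) return(skull$filled & FALSE)
  skull$filled & !binary_erode(skull$filled, cross_kernel(), iterations)
}

#' @export
print.skull_model <- function(x, ...) {
  cat("Skull model:", x$brain_pixels, "brain pixels;",
      sprintf("distance threshold %.2f px\n", x$distance_threshold))
  invisible(x)
}
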