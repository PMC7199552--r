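#' Structuring elements
#'
#' `cross_kernel()` is the 3x3 cross (city-block unit ball) used to expand
#' the skull edge inward. `disk_kernel(r)` is the discrete Euclidean disk:
#' all integer offsets with norm at most `r`; radius 0 is the single-pixel
#' identity element.
#'
#' @param r non-negative integer radius.
#' @return numeric 0/1 matrix with the anchor at the geometric center.
#' @export
cross_kernel <- function() {
  matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L, 3L)
}

#' @rdname cross_kernel
#' @export
disk_kernel <- function(r) {
  if (r < 0) stop("disk radius must be non-negative", call. = FALSE)
  r <- as.integer(r)
  if (r == 0L) return(matrix(1, 1L, 1L))
  o <- -r:r
  (outer(o, o, function(i, j) i * i + j * j) <= r * r) * 1
}

#' Binary erosion with explicit out-of-image background
#'
#' Pixels outside the image are treated as background, so objects touching
#' the border erode there too. Erosion is applied `iterations` times.
#'
#' @param mask logical matrix.
#' @param kern 0/1 structuring element (odd dimensions).
#' @param iterations number of passes (0 returns the mask unchanged).
#' @return logical matrix.
#' @export
binary_erode <- function(mask, kern, iterations = 1L) {
  assert_mask(mask)
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0", call. = FALSE)
  if (iterations == 0L || all(dim(kern) == 1L)) return(mask)
  pr <- (nrow(kern) - 1L) %/% 2L
  pc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L * pr * iterations, nc + 2L * pc * iterations)
  ri <- pr * iterations + seq_len(nr)
  ci <- pc * iterations + seq_len(nc)
  pad[ri, ci] <- mask * 1
  for (i in seq_len(iterations)) pad <- EBImage::erode(pad, kern)
  pad[ri, ci] > 0.5
}

#' Box-mean (averaging) filter with reflected borders
#'
#' @param img numeric matrix.
#' @param k odd kernel size; `k = 1` is the identity.
#' @return filtered matrix, same shape.
#' @export
box_mean <- function(img, k = 3L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("kernel size must be odd", call. = FALSE)
  if (k == 1L) return(img)
  p <- (k - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  if (p >= nr || p >= nc)
    stop("kernel larger than image", call. = FALSE)
  ridx <- c(p:1, 1:nr, nr:(nr - p + 1L))
  cidx <- c(p:1, 1:nc, nc:(nc - p + 1L))
  pad <- img[ridx, cidx, drop = FALSE]
  out <- EBImage::filter2(pad, matrix(1 / (k * k), k, k),
                          boundary = "circular")
  out <- as_plain_matrix(out)
  out <- out[p + seq_len(nr), p + seq_len(nc), drop = FALSE]
  # a mean cannot leave the input range; clip FFT round-off back into it
  pmin(pmax(out, min(img)), max(img))
}

# EBImage operations may return Image objects; keep plain matrices inside
# the package.
as_plain_matrix <- function(x) {
  d <- dim(x)
  matrix(as.numeric(x), d[1], d[2])
}
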