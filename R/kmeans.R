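#' k-means clustering of pixel intensities
#'
#' Lloyd iteration on the 1-D intensity feature: every pixel is assigned to
#' its nearest centroid, centroids are re-estimated as cluster means, and the
#' loop stops when the largest centroid shift falls below `tol` or after
#' `max_iter` iterations. With `k = 3` the clusters separate the slice into
#' dark (background), medium (cerebrum) and bright (skull and possible
#' tumors) regions.
#'
#' Initialization is deterministic: centroids start at the
#' \eqn{(2j - 1) / 2k} intensity quantiles, so repeated runs are
#' bit-identical without any RNG. An empty cluster is re-seeded at the pixel
#' farthest from its current centroid.
#'
#' The within-cluster sum of squares
#' \eqn{SSW = \sum_i (x_i - c_{k(i)})^2} is recorded after every assignment
#' step (`ssw_trace`); it is non-increasing across Lloyd iterations. The
#' between-cluster sum \eqn{SSB = \sum_j n_j (c_j - \bar x)^2} complements it:
#' SSW + SSB equals the total sum of squares.
#'
#' @param img grayscale matrix in \eqn{[0, 1]}.
#' @param k number of clusters (>= 1).
#' @param max_iter iteration cap.
#' @param tol centroid-shift stopping tolerance (normalized intensity).
#' @return object of class `intensity_km`: `k`, `centroids` (sorted
#'   ascending), `assignment` (integer matrix, 1..k), `n_j`,
#'   `overall_centroid`, `n_total`, `ssw_trace`, `iterations`.
#' @export
km_intensity <- function(img, k = 3L, max_iter = 100L, tol = 1e-4) {
  assert_gray_image(img)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  x <- as.vector(img)
  n <- length(x)
  centroids <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                               names = FALSE)
  # collapse of quantile seeds on heavily tied data: spread by tiny offsets
  # so all k seeds are distinct
  if (anyDuplicated(centroids))
    centroids <- centroids + (seq_len(k) - 1) * 1e-9
  ssw_trace <- numeric(0)
  assign_idx <- NULL
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    d <- abs(outer(x, centroids, "-"))
    assign_idx <- max.col(-d, ties.method = "first")
    # re-seed empty clusters at the pixel farthest from its centroid,
    # drawing only from clusters that keep at least one member (so heavily
    # tied or constant images cannot starve the repair)
    counts <- tabulate(assign_idx, nbins = k)
    if (any(counts == 0L)) {
      ord <- order(abs(x - centroids[assign_idx]), decreasing = TRUE)
      for (j in which(counts == 0L)) {
        donor <- ord[counts[assign_idx[ord]] > 1L][1L]
        if (is.na(donor)) break  # fewer pixels than clusters
        counts[assign_idx[donor]] <- counts[assign_idx[donor]] - 1L
        centroids[j] <- x[donor]
        assign_idx[donor] <- j
        counts[j] <- 1L
      }
    }
    ssw_trace <- c(ssw_trace, sum((x - centroids[assign_idx])^2))
    new_centroids <- vapply(seq_len(k), function(j) {
      xs <- x[assign_idx == j]
      if (length(xs)) mean(xs) else centroids[j]
    }, numeric(1))
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift < tol) break
  }
  ord <- order(centroids)
  centroids <- centroids[ord]
  assign_idx <- match(assign_idx, ord)
  structure(
    list(k = k,
         centroids = centroids,
         assignment = matrix(assign_idx, nrow(img), ncol(img)),
         n_j = tabulate(assign_idx, nbins = k),
         overall_centroid = mean(x),
         n_total = n,
         ssw_trace = ssw_trace,
         iterations = iterations),
    class = "intensity_km"
  )
}

#' Within- and between-cluster sums of squares
#'
#' `ssw()` returns \eqn{\sum_i (x_i - c_{k(i)})^2} over all pixels; `ssb()`
#' returns \eqn{\sum_j n_j (c_j - \bar x)^2}. Low SSW means cohesive
#' clusters; high SSB means well-separated clusters, and SSW + SSB equals
#' the total sum of squares about the overall mean.
#'
#' @param model fitted `intensity_km`.
#' @param img the image the model was fitted on.
#' @return numeric scalar.
#' @export
ssw <- function(model, img) {
  stopifnot(inherits(model, "intensity_km"))
  if (!identical(dim(img), dim(model$assignment)))
    stop("image shape does not match the fitted model", call. = FALSE)
  sum((as.vector(img) - model$centroids[as.vector(model$assignment)])^2)
}

#' @rdname ssw
#' @export
ssb <- function(model) {
  stopifnot(inherits(model, "intensity_km"))
  sum(model$n_j * (model$centroids - model$overall_centroid)^2)
}

#' Dark / medium / bright cluster masks
#'
#' For a `k = 3` model, returns the three disjoint masks ordered by
#' ascending centroid; their union covers the image.
#'
#' @param model fitted `intensity_km` with `k = 3`.
#' @return named list of logical matrices `dark`, `medium`, `bright`.
#' @export
cluster_masks <- function(model) {
  stopifnot(inherits(model, "intensity_km"))
  if (model$k != 3L)
    stop("cluster_masks requires a k = 3 model", call. = FALSE)
  list(dark = model$assignment == 1L,
       medium = model$assignment == 2L,
       bright = model$assignment == 3L)
}

#' @export
print.intensity_km <- function(x, ...) {
  cat("Intensity k-means: k =", x$k, "|", x$iterations, "iteration(s)\n")
  cat("Centroids:", paste(sprintf("%.4f", x$centroids), collapse = ", "), "\n")
  cat("Cluster sizes:", paste(x$n_j, collapse = ", "),
      "of", x$n_total, "pixels\n")
  invisible(x)
}
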