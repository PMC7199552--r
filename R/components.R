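#' Label connected components
#'
#' Foreground components are labelled 1, 2, ... in column-major scan order;
#' background is 0. Foreground adjacency defaults to 8-connectivity (the
#' convention used throughout the detector); hole filling uses the dual
#' 4-connected background.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  cc_label_cpp(mask, as.integer(connectivity))
}

#' Count binary objects
#'
#' An object is a group of bright pixels forming an 8-connected component
#' of a binary image.
#'
#' @param mask logical matrix.
#' @return integer component count (0 for an empty mask).
#' @export
count_objects <- function(mask) {
  max(label_components(mask, 8L))
}

#' Remove objects smaller than a pixel-area cutoff
#'
#' @param mask logical matrix.
#' @param min_area smallest object area (pixels) kept.
#' @return logical matrix with small components cleared.
#' @export
remove_small_objects <- function(mask, min_area) {
  if (min_area <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_area
  out <- mask
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Fill holes in binary objects
#'
#' Background 4-connected components not reachable from the image border are
#' holes; they are set to foreground. This is the dual convention to the
#' 8-connected foreground used by [label_components()].
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled; never removes true pixels.
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  if (all(mask)) return(mask)
  bg <- !mask
  lab <- cc_label_cpp(bg, 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  mask | hole
}

#' Select the largest component of a mask
#'
#' Ties on area are broken by the topmost, then leftmost component centroid,
#' so the choice is deterministic.
#'
#' @param mask logical matrix with at least one true pixel.
#' @return logical matrix containing only the winning component.
#' @keywords internal
largest_component <- function(mask) {
  lab <- label_components(mask, 8L)
  n <- max(lab)
  if (n == 0L) stop("empty mask has no components", call. = FALSE)
  if (n == 1L) return(mask)
  lab_best <- pick_component(lab, seq_len(n))
  lab == lab_best
}

# Among candidate labels, pick by (1) largest area, (2) topmost centroid,
# (3) leftmost centroid.
pick_component <- function(lab, candidates) {
  if (length(candidates) == 1L) return(candidates)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  rows <- row(lab); cols <- col(lab)
  score <- vapply(candidates, function(l) {
    sel <- lab == l
    c(sizes[l], mean(rows[sel]), mean(cols[sel]))
  }, numeric(3))
  ord <- order(-score[1, ], score[2, ], score[3, ])
  candidates[ord[1L]]
}

# 0-based centroid/bbox/area summary of one labelled region, from its
# 1-based pixel indices in a matrix of given dim.
region_summary <- function(idx, shape) {
  r <- ((idx - 1L) %% shape[1]) + 1L
  c_ <- ((idx - 1L) %/% shape[1]) + 1L
  list(
    centroid = c(mean(r) - 1, mean(c_) - 1),
    bbox = c(min(r) - 1L, min(c_) - 1L, max(r), max(c_)),
    area = length(idx)
  )
}
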