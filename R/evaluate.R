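#' Minimum Euclidean distance from a candidate to the skull edge
#'
#' The exact Euclidean distance transform of the edge gives, for every
#' pixel, the distance to the nearest edge pixel; the minimum over the
#' candidate's pixels is returned. Measuring from the nearest candidate
#' pixel (rather than its centroid) means a large tumor leaning against the
#' skull is judged by its closest point.
#'
#' @param candidate,edge nonempty logical matrices of identical shape.
#' @return non-negative distance in pixels (0 when the masks overlap).
#' @export
min_distance_to_edge <- function(candidate, edge) {
  assert_mask(candidate, "candidate")
  assert_mask(edge, "edge", shape = dim(candidate))
  if (!any(candidate)) stop("candidate mask is empty", call. = FALSE)
  if (!any(edge)) stop("edge mask is empty", call. = FALSE)
  dt <- edge_distance_map(edge)
  min(dt[candidate])
}

# Exact Euclidean distance (pixels) from every pixel to the nearest edge
# pixel; edge pixels are at distance 0.
edge_distance_map <- function(edge) {
  as_plain_matrix(EBImage::distmap((!edge) * 1, metric = "euclidean"))
}

#' Build candidate regions from a selected-pixel mask
#'
#' Each 8-connected component of the mask becomes one candidate region with
#' its pixel indices, 0-based centroid and half-open bounding box.
#'
#' @param mask logical matrix of selected candidate pixels.
#' @return list of `candidate_region` entries (possibly empty).
#' @export
candidate_regions <- function(mask) {
  assert_mask(mask)
  lab <- label_components(mask, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  shape <- dim(mask)
  idx_by_label <- split(which(lab > 0L), lab[lab > 0L])
  lapply(seq_len(n), function(l) {
    idx <- idx_by_label[[as.character(l)]]
    s <- region_summary(idx, shape)
    structure(list(label = l, pixels = idx, shape = shape,
                   centroid = s$centroid, bbox = s$bbox, area = s$area,
                   min_edge_distance = NA_real_, accepted = NA),
              class = "candidate_region")
  })
}

#' Flag false tumors by distance to the skull edge
#'
#' Every candidate's minimum Euclidean distance to the largest surrounding
#' edge is computed; candidates closer than the brain-size-dependent
#' threshold are flagged as rejected (false tumors adjacent to the skull),
#' the rest as accepted. Nothing is dropped, so reports remain auditable.
#'
#' @param candidates list from [candidate_regions()].
#' @param skull a `skull_model` from [fill_and_measure()].
#' @return the candidate list with `min_edge_distance` and `accepted` set.
#' @export
evaluate_candidates <- function(candidates, skull) {
  stopifnot(inherits(skull, "skull_model"))
  if (!length(candidates)) return(candidates)
  dt <- edge_distance_map(skull$edge)
  lapply(candidates, function(cr) {
    cr$min_edge_distance <- min(dt[cr$pixels])
    cr$accepted <- cr$min_edge_distance >= skull$distance_threshold
    cr
  })
}

# Rebuild the full-size logical mask of one candidate region.
candidate_mask <- function(cr) {
  m <- matrix(FALSE, cr$shape[1], cr$shape[2])
  m[cr$pixels] <- TRUE
  m
}
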