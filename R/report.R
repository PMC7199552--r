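#' Construct a detection report
#'
#' A detection report lists every candidate tumor region found by
#' [detect_tumors()], both accepted and rejected, so that the false-tumor
#' rejection step can be audited from the report alone. Serialized
#' coordinates are 0-based (row, col) with half-open bounding boxes
#' `(rmin, cmin, rmax, cmax)`; this is the package-wide convention for
#' reports, while in-R matrix access is 1-based as usual.
#'
#' @param regions list of region entries; each entry has `label`,
#'   `centroid` (0-based, length 2), `bbox` (0-based half-open, length 4),
#'   `area` (pixels), `distance_to_skull` (pixels, may be `NA` before
#'   evaluation) and `accepted` (logical).
#' @param image_shape integer vector `(height, width)`.
#' @param config_digest text digest of the configuration that produced the
#'   report.
#' @param distance_threshold the skull-distance threshold (pixels) applied
#'   to the candidates, so acceptance is re-checkable from the report alone
#'   (`NA` when no brain was found).
#' @param flags character vector of warnings (e.g. `"no_brain_found"`).
#' @return object of class `detection_report`.
#' @export
detection_report <- function(regions, image_shape, config_digest = "",
                             distance_threshold = NA_real_,
                             flags = character()) {
  image_shape <- as.integer(image_shape)
  for (r in regions) {
    stopifnot(r$area >= 1L)
    bb <- r$bbox
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > image_shape[1] ||
        bb[4] > image_shape[2] || bb[1] >= bb[3] || bb[2] >= bb[4])
      stop("region bbox lies outside image_shape", call. = FALSE)
  }
  structure(
    list(regions = regions, image_shape = image_shape,
         config_digest = config_digest,
         distance_threshold = as.numeric(distance_threshold),
         flags = flags),
    class = "detection_report"
  )
}

region_entry <- function(label, centroid, bbox, area,
                         distance_to_skull = NA_real_, accepted = NA) {
  list(label = as.integer(label), centroid = as.numeric(centroid),
       bbox = as.integer(bbox), area = as.integer(area),
       distance_to_skull = as.numeric(distance_to_skull),
       accepted = accepted)
}

#' Write / read a detection report as JSON
#'
#' Reports round-trip losslessly: `read_report(write_report(r, f))` equals
#' `r` up to numeric serialization precision (17 significant digits).
#'
#' @param report a [detection_report()].
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  payload <- list(
    regions = lapply(report$regions, function(r) {
      r$distance_to_skull <-
        if (is.na(r$distance_to_skull)) NULL else r$distance_to_skull
      r
    }),
    image_shape = report$image_shape,
    config_digest = report$config_digest,
    distance_threshold = if (is.na(report$distance_threshold)) NULL else
      report$distance_threshold,
    flags = as.list(report$flags)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report` returns a `detection_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("cannot read report: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  regions <- lapply(payload$regions, function(r) {
    region_entry(
      label = r$label,
      centroid = unlist(r$centroid),
      bbox = unlist(r$bbox),
      area = r$area,
      distance_to_skull = if (is.null(r$distance_to_skull)) NA_real_
                          else r$distance_to_skull,
      accepted = if (is.null(r$accepted)) NA else r$accepted
    )
  })
  detection_report(regions, unlist(payload$image_shape),
                   config_digest = payload$config_digest,
                   distance_threshold = payload$distance_threshold %||%
                     NA_real_,
                   flags = unlist(payload$flags, use.names = FALSE) %||%
                     character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.detection_report <- function(x, ...) {
  n_acc <- sum(vapply(x$regions, function(r) isTRUE(r$accepted), logical(1)))
  cat("Detection report:", length(x$regions), "candidate region(s),",
      n_acc, "accepted\n")
  cat("Image shape:", paste(x$image_shape, collapse = " x "), "\n")
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  for (r in x$regions) {
    cat(sprintf(
      "  #%d centroid=(%.1f, %.1f) area=%d dist_to_skull=%s %s\n",
      r$label, r$centroid[1], r$centroid[2], r$area,
      ifelse(is.na(r$distance_to_skull), "NA",
             sprintf("%.2f", r$distance_to_skull)),
      if (isTRUE(r$accepted)) "ACCEPTED" else "rejected"))
  }
  invisible(x)
}
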