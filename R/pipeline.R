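#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end detector. All values have the
#' defaults used throughout the documentation; the whole object serializes
#' to/from a single YAML file ([write_config()], [read_config()]).
#'
#' @param k number of k-means intensity clusters.
#' @param kmeans_tol,kmeans_max_iter k-means stopping parameters.
#' @param edge_expand_iterations width (px) of the inward skull band.
#' @param distance_anchors two-column `(size, threshold)` anchor matrix for
#'   the brain-size to distance-threshold mapping.
#' @param min_distance_threshold floor (px) of that mapping.
#' @param preprocess a [preprocess_config()].
#' @param detection a [detection_params()].
#' @param patch_size patch side at native scale.
#' @param scale patch upscaling factor.
#' @param shifts list of `(row, col)` grid offsets.
#' @param min_votes votes required to keep a pixel.
#' @param original_image_pass also run the scanning passes on the raw
#'   normalized image (pooled into the same vote map). Off by default; see
#'   the methods vignette for why.
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 3L,
                            kmeans_tol = 1e-4,
                            kmeans_max_iter = 100L,
                            edge_expand_iterations = 10L,
                            distance_anchors = default_distance_anchors(),
                            min_distance_threshold = 3,
                            preprocess = preprocess_config(),
                            detection = detection_params(),
                            patch_size = 200L,
                            scale = 3L,
                            shifts = default_shifts(),
                            min_votes = 2L,
                            original_image_pass = FALSE,
                            log_level = "info") {
  structure(list(k = as.integer(k), kmeans_tol = kmeans_tol,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 edge_expand_iterations = as.integer(edge_expand_iterations),
                 distance_anchors = distance_anchors,
                 min_distance_threshold = min_distance_threshold,
                 preprocess = preprocess, detection = detection,
                 patch_size = as.integer(patch_size),
                 scale = as.integer(scale), shifts = shifts,
                 min_votes = as.integer(min_votes),
                 original_image_pass = isTRUE(original_image_pass),
                 log_level = log_level),
            class = "pipeline_config")
}

config_digest <- function(cfg) rlang::hash(unclass(cfg))

log_stage <- function(cfg, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S "), "[", level, "] ", ...)
}

#' Detect and localize tumors in one MRI slice
#'
#' Runs the full pipeline: (i) k-means intensity clustering into dark,
#' medium and bright regions; (ii) extraction of the largest surrounding
#' edge (skull) and (iii) the brain-size-dependent distance threshold;
#' (iv) construction of the cerebral mask and the contrast-focused modified
#' image; (v)-(vi) patch-based multi-threshold detection on 3x-upscaled
#' patches; (vii) optional extra passes on the raw normalized image;
#' (viii) pooling of the 50-px-shifted passes with a minimum-vote rule; and
#' (ix) rejection of candidates closer to the skull edge than the distance
#' threshold. All candidates, accepted and rejected, are reported.
#'
#' An image without a detectable brain (e.g. an all-dark slice) yields an
#' empty report flagged `"no_brain_found"` rather than an error.
#'
#' @param img grayscale matrix in \eqn{[0, 1]} (see [load_image()]).
#' @param cfg a [pipeline_config()].
#' @param keep_masks also return the intermediate masks (candidate mask,
#'   accepted mask, skull model) in an `intermediates` attribute.
#' @return a [detection_report()].
#' @export
detect_tumors <- function(img, cfg = pipeline_config(), keep_masks = FALSE) {
  assert_gray_image(img)
  digest <- config_digest(cfg)
  empty_report <- function(flag) {
    log_stage(cfg, "warn", "pipeline stopped: ", flag)
    detection_report(list(), dim(img), digest, flags = flag)
  }

  km <- km_intensity(img, k = cfg$k, max_iter = cfg$kmeans_max_iter,
                     tol = cfg$kmeans_tol)
  log_stage(cfg, "info", "k-means: centroids ",
            paste(sprintf("%.3f", km$centroids), collapse = ", "))
  masks <- cluster_masks(km)

  skull <- tryCatch({
    edge <- largest_surrounding_edge(masks$bright, masks$medium)
    fill_and_measure(edge, cfg$distance_anchors, cfg$min_distance_threshold)
  }, error = function(e) NULL)
  if (is.null(skull)) return(empty_report("no_brain_found"))
  log_stage(cfg, "info", "skull: ", skull$brain_pixels, " brain px, ",
            sprintf("distance threshold %.2f px", skull$distance_threshold))

  band <- expand_edge_inward(skull, cfg$edge_expand_iterations)
  cereb <- tryCatch(cerebral_mask(masks$medium, band),
                    error = function(e) NULL)
  if (is.null(cereb)) return(empty_report("no_cerebral_tissue"))
  mod <- modified_image(img, cereb, cfg$preprocess)
  log_stage(cfg, "info", "modified image: ", sum(mod > 0), " nonzero px")

  vm <- run_passes(mod, cfg$detection, cfg$shifts, cfg$patch_size,
                   cfg$scale)
  if (cfg$original_image_pass) {
    vm_orig <- run_passes(img, cfg$detection, cfg$shifts, cfg$patch_size,
                          cfg$scale)
    vm <- pool_votes(vm, vm_orig)
  }
  log_stage(cfg, "info", "votes: max ", max(vm$votes), " over ",
            vm$n_passes, " pass(es)")

  selected <- select_candidates(vm, cfg$min_votes)
  cands <- candidate_regions(selected)
  log_stage(cfg, "info", "candidates: ", length(cands), " region(s)")
  cands <- evaluate_candidates(cands, skull)
  n_acc <- sum(vapply(cands, function(x) isTRUE(x$accepted), logical(1)))
  log_stage(cfg, "info", "accepted: ", n_acc, " region(s)")

  regions <- lapply(cands, function(cr)
    region_entry(cr$label, cr$centroid, cr$bbox, cr$area,
                 cr$min_edge_distance, cr$accepted))
  report <- detection_report(regions, dim(img), digest,
                             distance_threshold = skull$distance_threshold)
  if (keep_masks) {
    acc_mask <- matrix(FALSE, nrow(img), ncol(img))
    for (cr in cands) if (isTRUE(cr$accepted)) acc_mask[cr$pixels] <- TRUE
    attr(report, "intermediates") <- list(
      skull = skull, cerebral_mask = cereb, modified = mod,
      vote_map = vm, candidate_mask = selected, accepted_mask = acc_mask,
      kmeans = km)
  }
  report
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  payload <- unclass(cfg)
  payload$preprocess <- unclass(payload$preprocess)
  payload$detection <- unclass(payload$detection)
  payload$distance_anchors <- lapply(
    seq_len(nrow(cfg$distance_anchors)),
    function(i) as.numeric(cfg$distance_anchors[i, ]))
  payload$shifts <- lapply(cfg$shifts, as.integer)
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  anchors <- do.call(rbind, y$distance_anchors)
  colnames(anchors) <- c("size", "threshold")
  pipeline_config(
    k = y$k, kmeans_tol = y$kmeans_tol, kmeans_max_iter = y$kmeans_max_iter,
    edge_expand_iterations = y$edge_expand_iterations,
    distance_anchors = anchors,
    min_distance_threshold = y$min_distance_threshold,
    preprocess = do.call(preprocess_config, y$preprocess),
    detection = do.call(detection_params, y$detection),
    patch_size = y$patch_size, scale = y$scale,
    shifts = lapply(y$shifts, as.integer), min_votes = y$min_votes,
    original_image_pass = y$original_image_pass, log_level = y$log_level)
}
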