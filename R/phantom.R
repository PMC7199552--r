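#' Specify a synthetic brain-MRI phantom
#'
#' A phantom emulates the structures the detector relies on: a dark
#' background, a bright elliptical skull annulus, a medium-intensity
#' cerebral interior with additive Gaussian noise, planted bright tumors of
#' configurable size and intensity, and optional skull-adjacent bright
#' decoys ("false tumors") that a correct pipeline must reject. Tumors must
#' lie strictly inside the cerebrum; decoys must hug the skull ring.
#'
#' @param image_size `(height, width)` in pixels.
#' @param skull list: `center` (row, col), `semi_axes` (row, col semi-axes of
#'   the outer ellipse), `ring_thickness` (px), `intensity`.
#' @param cerebrum list: `base_intensity`, `noise_sigma`.
#' @param tumors list of `list(center, radius, intensity)`; radii >= 2.
#' @param decoys list of `list(center, radius, intensity)` near the ring.
#' @param background_intensity background level.
#' @param seed integer seed driving the cerebral noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512L, 512L),
                         skull = list(center = c(256, 256),
                                      semi_axes = c(190, 160),
                                      ring_thickness = 8,
                                      intensity = 0.9),
                         cerebrum = list(base_intensity = 0.40,
                                         noise_sigma = 0.03),
                         tumors = list(),
                         decoys = list(),
                         background_intensity = 0.02,
                         seed = 1L) {
  spec <- structure(
    list(image_size = as.integer(image_size), skull = skull,
         cerebrum = cerebrum, tumors = tumors, decoys = decoys,
         background_intensity = background_intensity,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  sk <- spec$skull
  inner <- sk$semi_axes - sk$ring_thickness
  for (tm in spec$tumors) {
    if (tm$radius < 2) stop("tumor radius must be >= 2", call. = FALSE)
    # tumor disk must fit strictly inside the cerebrum (inner ellipse)
    rho <- sqrt(sum(((tm$center - sk$center) /
                       (inner - tm$radius - 1))^2))
    if (!is.finite(rho) || rho >= 1)
      stop("tumor at (", tm$center[1], ", ", tm$center[2],
           ") does not lie strictly inside the cerebrum", call. = FALSE)
  }
  for (dc in spec$decoys) {
    if (dc$radius < 2) stop("decoy radius must be >= 2", call. = FALSE)
    # decoy center must sit within ring_thickness + 3 px of the skull ring
    rho <- sqrt(sum(((dc$center - sk$center) / sk$semi_axes)^2))
    slack <- (sk$ring_thickness + 3 + dc$radius) / min(sk$semi_axes)
    if (rho < 1 - sk$ring_thickness / min(sk$semi_axes) - slack ||
        rho > 1 + slack)
      stop("decoy at (", dc$center[1], ", ", dc$center[2],
           ") is not adjacent to the skull ring", call. = FALSE)
  }
  invisible(spec)
}

# Run code under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Render a phantom
#'
#' Background, skull annulus and noisy cerebral interior are rendered first;
#' tumor and decoy disks are composited with 1-px anti-aliased edges
#' (coverage-weighted blending). The ground-truth mask contains tumor pixels
#' with at least 50% disk coverage; decoys are excluded from the truth by
#' definition. Output is deterministic given the spec (which includes the
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `image` (grayscale matrix), `truth`
#'   (logical matrix), `metadata` (spec echo plus per-tumor pixel counts and
#'   the RNG used).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  sk <- spec$skull
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  f_outer <- ((rows - sk$center[1]) / sk$semi_axes[1])^2 +
    ((cols - sk$center[2]) / sk$semi_axes[2])^2
  inner <- sk$semi_axes - sk$ring_thickness
  f_inner <- ((rows - sk$center[1]) / inner[1])^2 +
    ((cols - sk$center[2]) / inner[2])^2
  img <- matrix(spec$background_intensity, h, w)
  ring <- f_outer <= 1 & f_inner > 1
  interior <- f_inner <= 1
  img[ring] <- sk$intensity
  noise <- with_seed(spec$seed, stats::rnorm(sum(interior), mean = 0,
                                             sd = spec$cerebrum$noise_sigma))
  img[interior] <- pmin(pmax(spec$cerebrum$base_intensity + noise, 0), 1)
  truth <- matrix(FALSE, h, w)
  tumor_px <- integer(length(spec$tumors))
  blend_disk <- function(img, blob) {
    d <- sqrt((rows - blob$center[1])^2 + (cols - blob$center[2])^2)
    cov <- pmin(pmax(blob$radius + 0.5 - d, 0), 1)
    img + cov * (blob$intensity - img)
  }
  for (i in seq_along(spec$tumors)) {
    tm <- spec$tumors[[i]]
    img <- blend_disk(img, tm)
    d <- sqrt((rows - tm$center[1])^2 + (cols - tm$center[2])^2)
    disk <- (tm$radius + 0.5 - d) >= 0.5  # coverage >= 50%
    truth <- truth | disk
    tumor_px[i] <- sum(disk)
  }
  for (dc in spec$decoys) img <- blend_disk(img, dc)
  img <- pmin(pmax(img, 0), 1)
  structure(
    list(image = img, truth = truth,
         metadata = list(spec = spec, tumor_pixels = tumor_px,
                         rng = "Mersenne-Twister/Inversion")),
    class = "phantom")
}

#' Fixed battery of eight test phantoms
#'
#' Deterministic suite covering the situations the detector must handle:
#' \enumerate{
#'   \item one large interior tumor (r = 25);
#'   \item one tiny tumor (r = 3);
#'   \item eight tumors of mixed sizes and intensities;
#'   \item tumors near, but beyond, the skull-distance threshold;
#'   \item skull-adjacent bright decoys only (empty truth);
#'   \item an empty brain;
#'   \item low-contrast tumors (intensity 0.55 on a 0.40 cerebrum);
#'   \item a tumor straddling a default 200-px patch boundary.
#' }
#' Per-phantom seeds are derived from `seed` so the battery is reproducible
#' end to end.
#'
#' @param seed integer master seed.
#' @return list of 8 `phantom` objects, in the order above.
#' @export
default_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  tum <- function(center, radius, intensity)
    list(center = center, radius = radius, intensity = intensity)
  specs <- list(
    large = phantom_spec(
      tumors = list(tum(c(256, 256), 25, 0.85)), seed = seed),
    tiny = phantom_spec(
      tumors = list(tum(c(230, 280), 3, 0.85)), seed = seed + 1L),
    mixed8 = phantom_spec(
      tumors = list(
        tum(c(160, 256), 4, 0.90), tum(c(200, 190), 7, 0.80),
        tum(c(200, 320), 3, 0.85), tum(c(256, 150), 12, 0.75),
        tum(c(256, 360), 9, 0.70), tum(c(256, 256), 20, 0.90),
        tum(c(330, 190), 16, 0.65), tum(c(340, 310), 5, 0.80)),
      seed = seed + 2L),
    near_threshold = phantom_spec(
      tumors = list(tum(c(256, 378), 6, 0.85), tum(c(106, 256), 8, 0.85)),
      seed = seed + 3L),
    decoys_only = phantom_spec(
      decoys = list(tum(c(424, 256), 5, 0.90), tum(c(169, 382), 5, 0.90),
                    tum(c(169, 130), 5, 0.90)),
      seed = seed + 4L),
    empty = phantom_spec(seed = seed + 5L),
    low_contrast = phantom_spec(
      tumors = list(tum(c(220, 220), 8, 0.55), tum(c(300, 300), 14, 0.55)),
      seed = seed + 6L),
    straddling = phantom_spec(
      tumors = list(tum(c(256, 200), 10, 0.85)), seed = seed + 7L)
  )
  lapply(specs, make_phantom)
}
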