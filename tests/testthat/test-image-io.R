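test_that("loading normalizes every supported format to [0, 1]", {
  # 8-bit PNG with the full 0..255 range divides by the range
  vals <- matrix(c(0, 64, 128, 255) / 255, 2, 2)
  f <- tempfile(fileext = ".png")
  png::writePNG(vals, f)
  img <- load_image(f)
  expect_equal(img, (vals - min(vals)) / diff(range(vals)))
  expect_equal(range(img), c(0, 1))

  # constant image maps to all zeros (degenerate range guarded)
  f2 <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 3, 3), f2)
  expect_equal(load_image(f2), matrix(0, 3, 3))

  # 16-bit TIFF with min 100, max 1100: pixel 600 maps to 0.5
  m <- matrix(c(100, 600, 1100, 100), 2, 2) / 65535
  f3 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, f3, bits.per.sample = 16L)
  img3 <- load_image(f3)
  expect_equal(img3[2, 1], 0.5, tolerance = 1e-6)
  expect_equal(img3[1, 2], 1)

  # RGB PNG collapses to luminance before normalizing
  arr <- array(stats::runif(2 * 3 * 3), dim = c(2, 3, 3))
  f4 <- tempfile(fileext = ".png")
  png::writePNG(arr, f4)
  img4 <- load_image(f4)
  expect_equal(dim(img4), c(2L, 3L))
  expect_true(all(img4 >= 0 & img4 <= 1))

  expect_error(load_image(tempfile(fileext = ".png")), "cannot read")
})

test_that("NIfTI volumes load one axial slice", {
  vol <- array(seq_len(4 * 5 * 3), dim = c(4, 5, 3))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  img <- load_image(f, slice_index = 2)
  expect_equal(img, normalize_minmax(vol[, , 2]))
  expect_error(load_image(f, slice_index = 9), "out of range")
  expect_error(load_image(f), "slice_index")
})

test_that("contrast stretch windows, clips and stays monotone", {
  set.seed(11)
  img <- matrix(stats::runif(100), 10, 10)
  # identity window leaves the image unchanged
  expect_equal(contrast_stretch(img, 0, 1), img)
  # idempotent under the identity window
  expect_equal(contrast_stretch(contrast_stretch(img, 0, 1), 0, 1), img)
  # the near-binarizing mid-intensity window
  expect_equal(contrast_stretch(matrix(0.6, 1, 1), 0.4999, 0.5001),
               matrix(1, 1, 1))
  expect_equal(contrast_stretch(matrix(0.5, 1, 1), 0.4999, 0.5001),
               matrix(0.5, 1, 1))
  expect_equal(contrast_stretch(matrix(0.2, 1, 1), 0.4999, 0.5001),
               matrix(0, 1, 1))
  # monotone non-decreasing in the input for a fixed window
  x <- matrix(sort(stats::runif(50)), 1)
  y <- contrast_stretch(x, 0.3, 0.7)
  expect_true(all(diff(as.vector(y)) >= 0))
  expect_error(contrast_stretch(img, 0.7, 0.3), "lo < hi")
})

test_that("masks round-trip through 8-bit PNG", {
  set.seed(7)
  mask <- random_mask(c(13, 9))
  f <- tempfile(fileext = ".png")
  write_mask(mask, f)
  expect_equal(read_mask(f), mask)
})

test_that("detection reports round-trip through JSON", {
  empty <- detection_report(list(), c(64, 64), "cfg0")
  f <- tempfile(fileext = ".json")
  write_report(empty, f)
  expect_equal(read_report(f), empty)

  regions <- lapply(1:8, function(i)
    list(label = i, centroid = c(10.5 + i, 20.25), bbox = c(i, 3L, i + 4L, 9L),
         area = 12L + i, distance_to_skull = 7.25 * i, accepted = i %% 2 == 0))
  rep8 <- detection_report(regions, c(64, 64), "cfgA",
                           distance_threshold = 6.5)
  write_report(rep8, f)
  back <- read_report(f)
  expect_equal(back, rep8)
  expect_equal(vapply(back$regions, `[[`, integer(1), "label"), 1:8)

  # bbox outside the image shape is rejected
  bad <- list(list(label = 1L, centroid = c(1, 1), bbox = c(0L, 0L, 70L, 4L),
                   area = 5L, distance_to_skull = NA_real_, accepted = NA))
  expect_error(detection_report(bad, c(64, 64)), "bbox")
})
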