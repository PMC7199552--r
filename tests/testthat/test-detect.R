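test_that("Otsu's threshold maximizes between-class variance", {
  # bimodal patch: the cut separates the two modes exactly
  x <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  t1 <- otsu_threshold(x)
  expect_true(t1 > 0.2 && t1 < 0.8)
  expect_equal(sum(x > t1), 50)
  # agreement with an exhaustive 256-bin scan on random patches
  set.seed(23)
  for (i in 1:5) {
    p <- matrix(stats::runif(400)^2, 20, 20)
    t_pkg <- otsu_threshold(p)
    t_ref <- exhaustive_otsu(p)
    # same class split even if the in-bin convention differs
    expect_equal(p > t_pkg, p > t_ref)
  }
  # histogram-only: invariant to pixel shuffling
  p <- matrix(stats::runif(144), 12, 12)
  shuffled <- matrix(sample(p), 12, 12)
  expect_equal(otsu_threshold(p), otsu_threshold(shuffled))
  expect_true(is.na(otsu_threshold(matrix(0.4, 5, 5))))
})

test_that("object counting matches the flood-fill oracle", {
  three <- disk_mask(c(40, 40), c(10, 10), 4) |
    disk_mask(c(40, 40), c(10, 30), 4) | disk_mask(c(40, 40), c(30, 20), 6)
  expect_equal(count_objects(three), 3L)
  expect_equal(count_objects(matrix(FALSE, 5, 5)), 0L)
  set.seed(29)
  for (i in 1:30) {
    m <- random_mask(c(30, 30), p = stats::runif(1, 0.1, 0.5))
    expect_equal(count_objects(m), bfs_count_objects(m, 8L))
  }
})

test_that("incremental-disk erosion stops at a single surviving object", {
  # already a single component: radius zero, identity
  one <- disk_mask(c(30, 30), c(15, 15), 6)
  r0 <- erode_until_single(one)
  expect_equal(r0$radius, 0L)
  expect_equal(r0$survivor, one)

  # a big and a small disk: the small one is eroded away first
  mask <- disk_mask(c(50, 50), c(20, 15), 10) | disk_mask(c(50, 50), c(20, 40), 2)
  res <- erode_until_single(mask)
  expect_true(res$radius >= 1L)
  expect_true(all(mask[res$survivor]))               # subset of the input
  expect_true(all(disk_mask(c(50, 50), c(20, 15), 10)[res$survivor]))
  # minimality: radius - 1 still leaves more than one object
  if (res$radius > 0) {
    prev <- binary_erode(mask, disk_kernel(res$radius - 1L))
    expect_gt(count_objects(prev), 1L)
  }

  # two equal disks vanish together: the jump-to-zero fallback applies
  twins <- disk_mask(c(40, 60), c(20, 15), 5) | disk_mask(c(40, 60), c(20, 45), 5)
  res2 <- erode_until_single(twins)
  expect_equal(count_objects(res2$survivor), 1L)
  expect_true(all(twins[res2$survivor]))
  expect_error(erode_until_single(matrix(FALSE, 5, 5)), "empty")
})

test_that("region growing floods the homogeneous neighborhood of the seed", {
  # unbounded tolerance on a bright image floods everything
  img <- matrix(0.8, 10, 10)
  expect_true(all(region_grow(img, c(5, 5), 1)))
  # zero tolerance on a flat disk recovers exactly the disk
  img2 <- matrix(0.1, 30, 30)
  disk <- disk_mask(c(30, 30), c(15, 15), 6)
  img2[disk] <- 0.9
  expect_equal(region_grow(img2, c(15, 15), 0), disk)
  # the grown region always contains the seed
  set.seed(37)
  for (i in 1:5) {
    img3 <- matrix(stats::runif(100), 10, 10)
    seed <- c(sample(10, 1), sample(10, 1))
    expect_true(region_grow(img3, seed, 0.2)[seed[1], seed[2]])
  }
  # the floor keeps a dim seed from engulfing the background
  img4 <- matrix(0.02, 20, 20)
  img4[10, 10] <- 0.12
  grown <- region_grow(img4, c(10, 10), 0.2, floor = 0.05)
  expect_equal(sum(grown), 1L)
  expect_error(region_grow(img2, c(0, 5), 0.1), "out of bounds")
})

test_that("patch detection finds bright objects and eliminates iteratively", {
  params <- detection_params()
  # an all-zero patch detects nothing
  expect_equal(detect_in_patch(matrix(0, 60, 60), params),
               matrix(FALSE, 60, 60))
  # a single bright disk is recovered with high overlap
  patch <- matrix(0.02, 120, 120)
  disk <- disk_mask(c(120, 120), c(60, 60), 12)
  patch[disk] <- 0.85
  det <- detect_in_patch(patch, params)
  inter <- sum(det & disk)
  dice <- 2 * inter / (sum(det) + sum(disk))
  expect_gte(dice, 0.8)
  # two disks of different brightness: the elimination loop finds both
  patch2 <- matrix(0.02, 120, 120)
  d1 <- disk_mask(c(120, 120), c(40, 40), 10)
  d2 <- disk_mask(c(120, 120), c(85, 85), 8)
  patch2[d1] <- 0.9
  patch2[d2] <- 0.55
  det2 <- detect_in_patch(patch2, params)
  expect_true(any(det2 & d1))
  expect_true(any(det2 & d2))
  # deterministic
  expect_identical(det2, detect_in_patch(patch2, params))
})

test_that("detection parameters validate their ranges", {
  expect_error(detection_params(thresholds = c(0, 0.5)), "thresholds")
  expect_error(detection_params(grow_delta = 1.2), "grow_delta")
  expect_error(detection_params(min_object_area = 0), "min_object_area")
})
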