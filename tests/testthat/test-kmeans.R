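test_that("clustering recovers point clusters and closed-form cases", {
  # data already in k point-clusters: zero within-cluster scatter
  img <- matrix(c(0, 0, 0.5, 0.5, 1, 1), 2, 3)
  m <- km_intensity(img, k = 3)
  expect_equal(m$centroids, c(0, 0.5, 1))
  expect_equal(ssw(m, img), 0)

  # the optimal 2-partition of {0.1, 0.2, 0.9, 1.0}
  img2 <- matrix(c(0.1, 0.2, 0.9, 1.0), 2, 2)
  m2 <- km_intensity(img2, k = 2)
  expect_equal(m2$centroids, c(0.15, 0.95))

  # k = 1 collapses to the overall mean
  set.seed(3)
  img3 <- matrix(stats::runif(64), 8, 8)
  m3 <- km_intensity(img3, k = 1)
  expect_equal(m3$centroids, mean(img3))
  expect_equal(ssb(m3), 0)

  expect_error(km_intensity(img, k = 0), "k must be")
})

test_that("SSW and SSB follow their definitions and decomposition", {
  # hand-computed SSW: {0.1, 0.2} about centroid 0.15
  img <- matrix(c(0.1, 0.2, 0.9, 1.0), 2, 2)
  m <- km_intensity(img, k = 2)
  expect_equal(ssw(m, img), 2 * 0.05^2 + 2 * 0.05^2)

  # hand-computed SSB: {0,0,1,1} with k = 2 about overall mean 0.5
  img2 <- matrix(c(0, 0, 1, 1), 2, 2)
  m2 <- km_intensity(img2, k = 2)
  expect_equal(ssb(m2), 1.0)

  # SSB homogeneity: scaling intensities by s scales SSB by s^2
  img3 <- matrix(c(0.1, 0.15, 0.8, 0.9, 0.85, 0.2), 2, 3)
  s <- 0.5
  expect_equal(ssb(km_intensity(img3 * s, k = 2)),
               s^2 * ssb(km_intensity(img3, k = 2)), tolerance = 1e-9)

  # within + between decomposition on random images
  set.seed(21)
  for (i in 1:5) {
    img4 <- matrix(stats::runif(400), 20, 20)
    m4 <- km_intensity(img4, k = 3)
    tss <- sum((img4 - mean(img4))^2)
    expect_equal(ssw(m4, img4) + ssb(m4), tss, tolerance = 1e-9)
  }
  expect_error(ssw(m2, matrix(0.5, 3, 3)), "shape")
})

test_that("Lloyd iterations never increase SSW and reach the k=2 optimum", {
  set.seed(42)
  for (i in 1:8) {
    img <- matrix(stats::runif(225), 15, 15)
    m <- km_intensity(img, k = 3)
    expect_true(all(diff(m$ssw_trace) <= 1e-12))
  }
  # oracle equivalence on separated two-group samples (<= 12 values), the
  # regime the quantile initialization is built for; on arbitrary samples
  # Lloyd is a local optimizer, so the exhaustive minimum bounds it below
  for (i in 1:8) {
    x <- round(c(stats::runif(sample(3:6, 1), 0, 0.35),
                 stats::runif(sample(3:6, 1), 0.65, 1)), 2)
    img <- matrix(x, 1)
    m <- km_intensity(img, k = 2)
    expect_equal(ssw(m, img), exhaustive_k2_ssw(x), tolerance = 1e-12)
  }
  for (i in 1:8) {
    x <- round(stats::runif(sample(6:12, 1)), 2)
    img <- matrix(x, 1)
    expect_gte(ssw(km_intensity(img, k = 2), img),
               exhaustive_k2_ssw(x) - 1e-12)
  }
})

test_that("cluster masks partition the image in centroid order", {
  # three-level synthetic image: masks equal the level sets
  set.seed(5)
  levels <- c(0.05, 0.4, 0.9)
  img <- matrix(sample(levels, 300, replace = TRUE), 15, 20)
  m <- km_intensity(img, k = 3)
  masks <- cluster_masks(m)
  expect_equal(masks$dark, img == 0.05)
  expect_equal(masks$medium, img == 0.4)
  expect_equal(masks$bright, img == 0.9)
  # pairwise disjoint, union covers everything
  expect_false(any(masks$dark & masks$medium))
  expect_false(any(masks$dark & masks$bright))
  expect_false(any(masks$medium & masks$bright))
  expect_true(all(masks$dark | masks$medium | masks$bright))
  expect_error(cluster_masks(km_intensity(img, k = 2)), "k = 3")
})

test_that("degenerate images cluster without stalling", {
  m <- km_intensity(matrix(0, 6, 6), k = 3)
  expect_equal(sum(m$n_j), 36L)
  expect_equal(length(m$centroids), 3L)
  m2 <- km_intensity(matrix(c(0, 1), 4, 4), k = 3)
  expect_equal(sum(m2$n_j), 16L)
})
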