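# Hand-crafted feature extractors and the seeded random forest.

test_that("GLCM features behave on constant and checkerboard images", {
  const <- matrix(100, 12, 12)
  f <- glcm_features(const)
  expect_equal(unname(f[grep("^energy", names(f))]), rep(1, 4))
  expect_equal(unname(f[grep("^contrast", names(f))]), rep(0, 4))
  # checkerboard at 2 levels, offset (0,1): all transitions, contrast 1
  cb <- matrix(rep(c(0, 255), 8), 4, 4)
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) * 255)
  f2 <- glcm_features(cb, levels = 2, offsets = list(c(0, 1)))
  expect_equal(unname(f2[["contrast_0_1"]]), 1)
  expect_equal(unname(f2[["energy_0_1"]]), 0.5)   # mass split off-diagonal
  set.seed(51)
  img <- matrix(sample(0:255, 144, replace = TRUE), 12)
  # normalization: rebuild one matrix by hand and compare a feature
  f3 <- glcm_features(img, levels = 8, offsets = list(c(1, 0)))
  expect_true(all(is.finite(f3)))
})

test_that("Gabor features have the right length and orientation selectivity", {
  expect_length(gabor_features(matrix(0, 16, 16),
                               frequencies = c(0.1, 0.2, 0.3, 0.4),
                               orientations = seq(0, pi,
                                                  length.out = 7)[-7]), 48)
  const <- matrix(50, 16, 16)
  f <- gabor_features(const)
  expect_equal(unname(f[grep("^var", names(f))]),
               rep(0, length(f) / 2), tolerance = 1e-9)
  # vertical stripes (varying along columns) excite orientation 0
  stripes <- matrix(rep(127 + 120 * sin(2 * pi * 0.2 * (1:32)), each = 32),
                    32, 32)
  fs <- gabor_features(stripes, frequencies = 0.2,
                       orientations = c(0, pi / 2))
  expect_gt(fs[["mean_f0.20_t0.00"]], fs[["mean_f0.20_t1.57"]])
})

test_that("LBP histograms are normalized and rotation-invariant", {
  const <- matrix(77, 16, 16)
  h <- lbp_histogram(const, radius = 3, n_points = 8)
  # no local contrast: all-ones pattern (neighbour >= center everywhere)
  expect_equal(unname(h[9]), 1)     # bin '8 ones' out of bins 0..8 + other
  set.seed(52)
  img <- matrix(runif(400, 0, 255), 20)
  h1 <- lbp_histogram(img)
  expect_equal(sum(h1), 1, tolerance = 1e-12)
  expect_equal(h1, lbp_histogram(rotate_image(img, 90)), tolerance = 1e-12)
})

test_that("intensity histograms count, normalize and reject bad colourspaces", {
  g <- matrix(128, 10, 10)
  hg <- intensity_histograms(g, "gray", bins = 16)
  expect_length(hg, 16)
  expect_equal(sum(hg == 1), 1)
  expect_equal(sum(hg), 1)
  rgb <- array(runif(300, 0, 255), c(10, 10, 3))
  expect_length(intensity_histograms(rgb, "RGB", bins = 8), 24)
  expect_length(intensity_histograms(rgb, "HSV", bins = 8), 24)
  expect_error(intensity_histograms(g, "RGB"), "RGB input")
  # histograms discard geometry
  perm <- matrix(sample(as.vector(rgb[, , 1])), 10, 10)
  expect_equal(intensity_histograms(perm, "gray", 16),
               intensity_histograms(rgb[, , 1], "gray", 16))
})

test_that("random forest is seeded, normalized and fits separable features", {
  set.seed(53)
  n <- 60
  X <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 3), n, 4))
  y <- rep(c("benign", "BPH"), each = n)
  rf <- train_rf(X, y, n_trees = 100, seed = 1)
  cl <- classify_rf(rf, X)
  expect_gte(mean(cl$labels == y), 0.95)
  expect_equal(rowSums(cl$scores), rep(1, 2 * n), tolerance = 1e-12)
  rf2 <- train_rf(X, y, n_trees = 100, seed = 1)
  expect_identical(classify_rf(rf2, X)$scores, cl$scores)
  expect_error(train_rf(X, rep("BPH", 2 * n)), "2 classes")
  # column order contract: P(BPH) is the last column
  expect_identical(colnames(cl$scores), c("benign", "BPH"))
})
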