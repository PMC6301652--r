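# Binarization front end: grayscale conversion, median filtering, the
# iterative two-threshold split, morphology, size filtering, patch
# extraction and negative mining.

test_that("rgb_to_gray applies the 601 luma weights with half-up rounding", {
  white <- array(255, c(2, 2, 3))
  expect_true(all(rgb_to_gray(white) == 255))
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(as.numeric(rgb_to_gray(red)), 76)   # 0.299 * 255 = 76.245
  expect_true(all(rgb_to_gray(array(0, c(3, 3, 3))) == 0))
  expect_error(rgb_to_gray(matrix(0, 3, 3)), "RGB")
})

test_that("median filter matches the brute-force oracle and suppresses salt noise", {
  expect_error(median_filter(matrix(1, 5, 5), 4), "odd")
  const <- matrix(7, 6, 6)
  expect_identical(median_filter(const, 3), const)
  flat <- matrix(10, 9, 9); flat[5, 5] <- 255
  expect_equal(median_filter(flat, 3)[5, 5], 10)
  set.seed(21)
  img <- matrix(sample(0:255, 256, replace = TRUE), 16)
  got <- median_filter(img, 3)
  ref <- brute_median_interior(img, 3)
  inner <- 2:15
  expect_identical(got[inner, inner], ref[inner, inner])
})

test_that("iterative thresholds separate a trimodal image and handle degenerate input", {
  img <- matrix(rep(c(10, 100, 200), each = 100), 10, 30)
  tr <- iterative_multithreshold(img)
  expect_true(tr$t_low >= 10 && tr$t_low <= 99)
  expect_true(tr$t_high >= 100 && tr$t_high <= 199)
  expect_true(tr$converged)
  expect_gte(tr$variance, tr$variance_init)
  # constant-plus-two-outliers still converges
  deg <- matrix(128, 8, 8); deg[1, 1] <- 0; deg[8, 8] <- 255
  tr2 <- iterative_multithreshold(deg)
  expect_true(tr2$converged)
  expect_lte(tr2$iterations, 100)
  expect_error(iterative_multithreshold(matrix(c(0, 255), 4, 4)),
               "3 distinct")
})

test_that("binarize selects the class named by the foreground rule", {
  img <- matrix(c(40, 200, 100, 70), 2, 2)
  thr <- list(t_low = 50, t_high = 150)
  dark <- binarize(img, thr, "darkest")
  expect_identical(as.vector(dark), c(TRUE, FALSE, FALSE, FALSE))
  tri <- matrix(rep(c(10, 100, 200), 3), 3, 3)
  thr2 <- list(t_low = 50, t_high = 150)
  mid <- binarize(tri, thr2, "middle")
  expect_identical(mid, tri == 100)
  expect_identical(binarize(tri, thr2, "brightest"), tri == 200)
})

test_that("closing/opening fixes sub-element defects and is idempotent on smooth shapes", {
  sq <- matrix(FALSE, 26, 26); sq[4:23, 4:23] <- TRUE
  expect_identical(morph_close_open(sq, 1), sq)
  holey <- sq; holey[12, 12] <- FALSE
  expect_identical(morph_close_open(holey, 1), sq)
  speck <- matrix(FALSE, 15, 15); speck[8, 8] <- TRUE
  expect_false(any(morph_close_open(speck, 1)))
  # idempotence on shapes already smooth at the element scale
  disk <- disk_mask(40, 40, 20, 20, 11)
  once <- morph_close_open(disk, 1)
  expect_identical(morph_close_open(once, 1), once)
})

test_that("size_filter drops exactly the small components", {
  m <- matrix(FALSE, 30, 40)
  m[2:4, 2:3] <- TRUE                       # area 6
  m[10:16, 5:12] <- TRUE                    # area 56
  m[22:29, 20:35] <- TRUE                   # area 128
  out <- size_filter(m, min_area = 10)
  expect_identical(sort(component_areas(out)), c(56L, 128L))
  expect_identical(size_filter(m, 0), m)
  set.seed(22)
  for (i in 1:10) {
    r <- random_mask(20, 20, 0.4)
    out <- size_filter(r, 4)
    expect_true(all(!out | r))
    expect_identical(sort(component_areas(out)),
                     sort(component_areas(r)[component_areas(r) >= 4]))
  }
})

test_that("extract_patch crops 2r squares, preserves identity scale, pads at borders", {
  set.seed(23)
  img <- matrix(sample(0:255, 300 * 300, replace = TRUE), 300)
  ann <- list(image_id = "x", center_row = 150, center_col = 150,
              radius = 56, label = "BPH")
  p <- extract_patch(img, ann, 224)
  expect_equal(dim(p$pixels), c(224, 224))
  expect_false(p$source$padded)
  # radius = out_size / 2: no resampling at all
  ann2 <- list(image_id = "x", center_row = 100, center_col = 80,
               radius = 16, label = "benign")
  p2 <- extract_patch(img, ann2, 32)
  crop <- img[(100 - 16 + 1):(100 + 16) + 1, (80 - 16 + 1):(80 + 16) + 1]
  expect_identical(p2$pixels, crop)
  # corner annotation: still full size, flagged padded
  ann3 <- list(image_id = "x", center_row = 2, center_col = 2, radius = 10,
               label = "BPH")
  p3 <- extract_patch(img, ann3, 21)
  expect_equal(dim(p3$pixels), c(21, 21))
  expect_true(p3$source$padded)
})

test_that("full chain on a clean scene recovers the inserted insects (IoU >= 0.7 each)", {
  cfg <- scene_config(512, 512, 5, 5, distortion = 0, illum_gradient = 0.2,
                      speck_density = 50, noise_sd = 5, seed = 1)
  sc <- generate_scene(cfg)
  gray <- rgb_to_gray(sc$image)
  mask <- binarize_chain(gray)
  ious <- vapply(seq_len(nrow(sc$truth)), function(i) {
    ann <- sc$truth[i, ]
    r <- ann$radius
    rows <- (ann$center_row - r + 1):(ann$center_row + r) + 1
    cols <- (ann$center_col - r + 1):(ann$center_col + r) + 1
    sub <- gray[rows, cols]
    msub <- mask[rows, cols]
    ref <- sub < 140          # insects are dark, the pad is pale
    sum(msub & ref) / sum(msub | ref)
  }, 0)
  expect_true(all(ious >= 0.7))
  expect_gte(mean(ious), 0.9)
})

test_that("negative mining returns only patches clear of planthopper circles", {
  blank <- matrix(128, 64, 64)
  no_ann <- data.frame(image_id = character(), center_row = numeric(),
                       center_col = numeric(), radius = numeric(),
                       label = character())
  expect_length(mine_negative_patches(blank, no_ann, patch_size = 21), 0)
  sc <- generate_scene(scene_config(256, 256, 3, 3, distortion = 0.3,
                                    seed = 5))
  gray <- rgb_to_gray(sc$image)
  negs <- mine_negative_patches(gray, sc$truth, patch_size = 21,
                                max_patches = 15, seed = 2)
  expect_gt(length(negs), 0)
  bph <- sc$truth[sc$truth$label == "BPH", ]
  for (p in negs) {
    expect_identical(p$label, "benign")
    d <- sqrt((bph$center_row - p$source$center_row)^2 +
                (bph$center_col - p$source$center_col)^2)
    expect_true(all(d > bph$radius))
  }
  # an image whose only content is one annotated planthopper yields nothing
  one <- generate_scene(scene_config(128, 128, 1, 0, distortion = 0,
                                     speck_density = 0, noise_sd = 0,
                                     illum_gradient = 0, seed = 8))
  g1 <- rgb_to_gray(one$image)
  expect_length(mine_negative_patches(g1, one$truth, patch_size = 31,
                                      max_patches = 10, seed = 1), 0)
})
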