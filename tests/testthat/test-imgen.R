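# Synthetic scene generator: sprite morphology, scene assembly, dataset
# splits, determinism and the class-separability contract.

test_that("sprite classes have the intended aspect ratios and reject bad labels", {
  bph <- render_insect("BPH", 0, seed = 1)
  ben <- render_insect("benign", 0, seed = 1)
  expect_gte(aspect_from_moments(bph$mask), 2.0)
  expect_lte(aspect_from_moments(bph$mask), 3.5)
  expect_gte(aspect_from_moments(ben$mask), 1.0)
  expect_lte(aspect_from_moments(ben$mask), 1.6)
  expect_error(render_insect("wasp", 0), "unknown insect class")
  expect_error(render_insect("BPH", 1.5), "distortion")
})

test_that("distortion removes sprite area", {
  intact <- render_insect("BPH", 0, seed = 2)
  damaged <- render_insect("BPH", 1, seed = 2)
  expect_lt(sum(damaged$mask), sum(intact$mask))
  # roughly the targeted 30% sector is gone at full distortion
  expect_lt(sum(damaged$mask), 0.85 * sum(intact$mask))
})

test_that("generate_scene places the requested insects with in-bounds circles", {
  cfg <- scene_config(256, 256, 5, 5, distortion = 0.3, seed = 7)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth), 10)
  expect_equal(sum(sc$truth$label == "BPH"), 5)
  expect_equal(sum(sc$truth$label == "benign"), 5)
  # circles fully inside the scene (0-based coordinates)
  expect_true(all(sc$truth$center_row - sc$truth$radius >= 0))
  expect_true(all(sc$truth$center_col - sc$truth$radius >= 0))
  expect_true(all(sc$truth$center_row + sc$truth$radius <= 255))
  expect_true(all(sc$truth$center_col + sc$truth$radius <= 255))
  expect_equal(dim(sc$image), c(256, 256, 3))
  expect_true(all(sc$image >= 0 & sc$image <= 255))
})

test_that("an empty scene has empty ground truth and scenes are seed-deterministic", {
  cfg0 <- scene_config(128, 128, 0, 0, seed = 5)
  sc0 <- generate_scene(cfg0)
  expect_equal(nrow(sc0$truth), 0)
  cfg <- scene_config(192, 192, 3, 2, seed = 11)
  expect_identical(generate_scene(cfg)$image, generate_scene(cfg)$image)
  # overflow: too many insects for the area errors with the failing count
  expect_error(generate_scene(scene_config(96, 96, 30, 30, seed = 1)),
               "without overlap")
})

test_that("dataset split reproduces the published per-class sizes and rounding", {
  expect_identical(largest_remainder(337, c(0.7, 0.1, 0.2)),
                   c(236L, 34L, 67L))
  expect_identical(largest_remainder(350, c(0.7, 0.1, 0.2)),
                   c(245L, 35L, 70L))
  expect_identical(largest_remainder(10, c(0.8, 0.1, 0.1)), c(8L, 1L, 1L))
})

test_that("generate_dataset splits are stratified, deterministic and leakage-free", {
  ds <- generate_dataset(20, 25, split = c(0.6, 0.2, 0.2), patch_size = 21,
                         seed = 3)
  lab <- function(part) table(vapply(part, `[[`, "", "label"))
  expect_equal(as.integer(lab(ds$train)[c("BPH", "benign")]), c(12L, 15L))
  expect_equal(as.integer(lab(ds$val)[c("BPH", "benign")]), c(4L, 5L))
  expect_equal(as.integer(lab(ds$test)[c("BPH", "benign")]), c(4L, 5L))
  ids <- function(part) vapply(part, function(p) p$source$image_id, "")
  expect_length(intersect(ids(ds$train), ids(ds$test)), 0)
  expect_length(intersect(ids(ds$train), ids(ds$val)), 0)
  expect_length(intersect(ids(ds$val), ids(ds$test)), 0)
  ds2 <- generate_dataset(20, 25, split = c(0.6, 0.2, 0.2), patch_size = 21,
                          seed = 3)
  expect_identical(ids(ds$train), ids(ds2$train))
  expect_identical(ids(ds$test), ids(ds2$test))
  expect_error(generate_dataset(4, 4, split = c(0.9, 0.05, 0.05)),
               "0 items")
})

test_that("classes separate by a trivial moment feature at distortion 0.5 (>= 80% of 200 patches)", {
  patches <- make_patch_set(100, 100, distortion = 0.5, patch_size = 21,
                            seed = 9)
  lab <- vapply(patches, `[[`, "", "label")
  asp <- vapply(patches, function(p) {
    g <- if (length(dim(p$pixels)) == 3) rgb_to_gray(p$pixels) else p$pixels
    aspect_from_moments(binarize_chain(g, min_area = 10))
  }, 0)
  asp[is.na(asp)] <- 1
  # best single-threshold rule on the aspect ratio
  ths <- sort(unique(asp))
  acc <- max(vapply(ths, function(t) {
    mean(ifelse(asp >= t, "BPH", "benign") == lab)
  }, 0))
  expect_gte(acc, 0.8)
})

test_that("scene round-trips through PNG + CSV and plain-text PNM", {
  sc <- generate_scene(scene_config(96, 96, 1, 1, seed = 13))
  d <- withr::local_tempdir()
  write_scene(sc, file.path(d, "s.png"), file.path(d, "s.csv"))
  img <- read_image(file.path(d, "s.png"))
  expect_equal(dim(img), dim(sc$image))
  expect_lt(max(abs(img - round(sc$image))), 1.0)  # 8-bit quantization
  ann <- read_annotations(file.path(d, "s.csv"))
  expect_equal(nrow(ann), 2)
  write_pnm_path <- file.path(d, "s.ppm")
  write_image(sc$image, write_pnm_path)
  img2 <- read_image(write_pnm_path)
  expect_equal(img2, round_half_up(sc$image), tolerance = 1e-12)
})
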