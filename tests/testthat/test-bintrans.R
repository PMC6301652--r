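# Binary image models: outline, hole filling, skeleton, distance map,
# watershed, Voronoi, and the model dispatch table.

test_that("outline is the 1-pixel inner boundary", {
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  o <- outline(m)
  expect_equal(sum(o), 36)                       # 10x10 square frame
  expect_false(any(o[4:11, 4:11]))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(outline(single), single)
  set.seed(31)
  for (i in 1:5) {
    r <- random_blob_mask(20, 20, 3, 3)
    o <- outline(r)
    expect_true(all(!o | r))
    # interior (mask minus outline) has no pixel 4-adjacent to background
    interior <- r & !o
    for (p in which(interior)) {
      pi <- (p - 1) %% 20 + 1; pj <- (p - 1) %/% 20 + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- pi + d[1]; jj <- pj + d[2]
        if (ii >= 1 && ii <= 20 && jj >= 1 && jj <= 20) {
          expect_true(r[ii, jj])
        }
      }
    }
  }
})

test_that("fill_holes fills enclosed background only and is idempotent", {
  ring <- disk_mask(30, 30, 15, 15, 10) & !disk_mask(30, 30, 15, 15, 5)
  filled <- fill_holes(ring)
  expect_identical(filled, disk_mask(30, 30, 15, 15, 10))
  solid <- disk_mask(20, 20, 10, 10, 6)
  expect_identical(fill_holes(solid), solid)
  set.seed(32)
  for (i in 1:5) {
    r <- random_mask(18, 18, 0.5)
    f <- fill_holes(r)
    expect_true(all(f | !r))
    expect_identical(fill_holes(f), f)
  }
})

test_that("skeletonize thins a bar to a line and preserves components", {
  bar <- matrix(FALSE, 10, 30); bar[4:6, 5:25] <- TRUE
  sk <- skeletonize(bar)
  expect_equal(length(unique(which(sk, arr.ind = TRUE)[, 1])), 1)
  expect_true(all(colSums(sk) <= 1))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(skeletonize(single), single)
  set.seed(33)
  for (i in 1:10) {
    r <- random_blob_mask(24, 24, sample(2:5, 1), sample(2:4, 1))
    sk <- skeletonize(r)
    expect_true(all(!sk | r))
    expect_identical(count_components(sk, 8), count_components(r, 8))
  }
})

test_that("euclidean_distance_map is exact and rejects all-foreground masks", {
  m <- matrix(TRUE, 8, 8); m[1, 1] <- FALSE
  d <- euclidean_distance_map(m)
  expect_equal(d[4, 5], 5)                       # 3-4-5 triangle from (0,0)
  expect_equal(d[1, 1], 0)
  expect_error(euclidean_distance_map(matrix(TRUE, 4, 4)),
               "no background")
  set.seed(34)
  for (i in 1:10) {
    r <- random_mask(16, 16, 0.6)
    if (all(r)) r[1, 1] <- FALSE
    expect_lt(max(abs(unclass(euclidean_distance_map(r)) - brute_edt(r))),
              1e-9)
  }
})

test_that("edm_to_gray rescales linearly with half-up rounding", {
  e <- matrix(c(0, 2.5, 5, 1), 2, 2)
  g <- edm_to_gray(e)
  expect_equal(g[1, 2], 255)                     # max -> 255
  expect_equal(g[2, 1], 128)                     # round(127.5) half-up
  expect_equal(edm_to_gray(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(35)
  e2 <- matrix(runif(64, 0, 9), 8, 8)
  expect_equal(which.max(edm_to_gray(e2)), which.max(e2))
})

test_that("watershed splits touching disks and never adds pixels", {
  m <- disk_mask(60, 90, 30, 30, 20) | disk_mask(60, 90, 30, 60, 20)
  expect_equal(count_components(m, 8), 1)
  ws <- watershed_binary(m)
  expect_equal(count_components(ws, 8), 2)
  expect_true(all(!ws | m))
  solo <- disk_mask(40, 40, 20, 20, 12)
  expect_identical(watershed_binary(solo), solo)
})

test_that("voronoi lines are equidistant background ridges", {
  m <- matrix(FALSE, 21, 41); m[11, 11] <- TRUE; m[11, 31] <- TRUE
  v <- voronoi(m)
  expect_gt(sum(v), 0)
  expect_false(any(v & m))
  w <- which(v, arr.ind = TRUE)
  # every line pixel is (near-)equidistant from the two particles
  d1 <- sqrt((w[, 1] - 11)^2 + (w[, 2] - 11)^2)
  d2 <- sqrt((w[, 1] - 11)^2 + (w[, 2] - 31)^2)
  expect_true(all(abs(d1 - d2) <= 2))
  expect_false(any(voronoi(disk_mask(20, 20, 10, 10, 5))))
})

test_that("apply_image_model dispatches and renders correctly", {
  mask <- disk_mask(21, 21, 11, 11, 6)
  f <- apply_image_model(mask, NULL, "F")
  expect_gt(length(unique(as.vector(f))), 2)     # EDM is non-binary
  expect_equal(max(f), 255)
  a <- apply_image_model(mask, NULL, "A")
  expect_true(all(a %in% c(0, 255)))
  rgb <- array(runif(21 * 21 * 3, 0, 255), c(21, 21, 3))
  expect_identical(apply_image_model(mask, rgb, "G"), rgb)
  expect_error(apply_image_model(mask, NULL, "Z"), "unknown image model")
  expect_error(apply_image_model(mask, NULL, "G"), "RGB")
})
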