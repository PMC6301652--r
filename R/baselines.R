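## Hand-crafted-feature baselines: co-occurrence (GLCM), Gabor filter bank,
## uniform rotation-invariant local binary patterns, and gray/HSV/RGB
## intensity histograms, each followed by a seeded random forest.  Feature
## extraction is fully deterministic; only the forest uses (seeded)
## randomness.

#' Gray-level co-occurrence features
#'
#' Quantizes the image to `levels` gray levels, builds one symmetrized,
#' sum-normalized co-occurrence matrix per offset, and emits contrast,
#' correlation, energy and homogeneity for each, concatenated across
#' offsets.
#'
#' @param img grayscale matrix (0-255).
#' @param levels number of gray levels (>= 2).
#' @param offsets list of `c(drow, dcol)` displacement vectors.
#' @return named numeric feature vector with attribute `scheme = "GLCM"`.
#' @export
glcm_features <- function(img, levels = 32,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1),
                                         c(1, -1))) {
  assert_gray(img)
  stopifnot(levels >= 2)
  q <- pmin(floor(clip01(img) / 256 * levels) + 1, levels)
  h <- nrow(q); w <- ncol(q)
  out <- numeric(0)
  for (o in offsets) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    a <- as.vector(q[r1, c1, drop = FALSE])
    b <- as.vector(q[r1 + dr, c1 + dc, drop = FALSE])
    P <- matrix(0, levels, levels)
    tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
    P <- P + tab + t(tab)                 # symmetrize
    P <- P / sum(P)
    i <- matrix(rep(1:levels, levels), levels, levels)
    j <- t(i)
    mu_i <- sum(i * P); mu_j <- sum(j * P)
    sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
    contrast <- sum((i - j)^2 * P)
    correlation <- if (sd_i > 0 && sd_j > 0) {
      sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
    } else 1   # constant image: perfectly correlated by convention
    energy <- sum(P^2)
    homogeneity <- sum(P / (1 + (i - j)^2))
    v <- c(contrast = contrast, correlation = correlation, energy = energy,
           homogeneity = homogeneity)
    names(v) <- paste0(names(v), "_", dr, "_", dc)
    out <- c(out, v)
  }
  structure(out, scheme = "GLCM")
}

gabor_kernel <- function(frequency, theta, sigma = 0.56 / frequency,
                         phase = 0) {
  r <- max(2L, ceiling(2.5 * sigma))
  y <- matrix(rep(-r:r, 2 * r + 1), 2 * r + 1)
  x <- t(y)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * frequency * xr + phase)
  # remove the DC component so a constant image gives zero response
  re <- re - env * sum(re) / sum(env)
  list(re = re, im = env * sin(2 * pi * frequency * xr + phase))
}

#' Gabor filter-bank features
#'
#' Convolves the image with a Gabor kernel for each (frequency,
#' orientation) pair and emits the mean and variance of the response
#' magnitude; the vector length is `2 * length(frequencies) *
#' length(orientations)`.
#'
#' @param img grayscale matrix.
#' @param frequencies spatial frequencies in cycles/pixel.
#' @param orientations orientations in radians (wave-vector direction;
#'   0 responds to intensity variation along columns).
#' @return named numeric feature vector with attribute `scheme = "Gabor"`.
#' @export
gabor_features <- function(img, frequencies = c(0.1, 0.2, 0.3, 0.4),
                           orientations = seq(0, pi, length.out = 7)[-7]) {
  assert_gray(img)
  stopifnot(length(frequencies) >= 1, length(orientations) >= 1)
  out <- numeric(0)
  for (f in frequencies) {
    for (th in orientations) {
      k <- gabor_kernel(f, th)
      re <- cpp_conv2_same(img, k$re, 1L)   # replicate border
      im <- cpp_conv2_same(img, k$im, 1L)
      mag <- sqrt(re^2 + im^2)
      v <- c(mean(mag), stats::var(as.vector(mag)))
      names(v) <- sprintf(c("mean_f%.2f_t%.2f", "var_f%.2f_t%.2f"), f, th)
      out <- c(out, v)
    }
  }
  structure(out, scheme = "Gabor")
}

#' Uniform rotation-invariant LBP histogram
#'
#' Local binary patterns on a circle of `n_points` bilinear-sampled
#' neighbours at `radius`; uniform patterns (at most two 0/1 transitions)
#' are binned by their number of set bits, all other patterns share one
#' bin, giving `n_points + 2` bins normalized to sum 1.
#'
#' @param img grayscale matrix.
#' @param radius circle radius in pixels.
#' @param n_points sampling points on the circle (>= 4).
#' @return numeric histogram of length `n_points + 2`, attribute
#'   `scheme = "LBP"`.
#' @export
lbp_histogram <- function(img, radius = 3, n_points = 24) {
  assert_gray(img)
  stopifnot(n_points >= 4)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(radius)
  if (h <= 2 * r || w <= 2 * r) {
    stop("image too small for LBP radius ", radius, call. = FALSE)
  }
  ri <- (r + 1):(h - r)
  ci <- (r + 1):(w - r)
  center <- img[ri, ci, drop = FALSE]
  np <- length(ri) * length(ci)
  bits <- matrix(0L, np, n_points)
  for (p in seq_len(n_points)) {
    a <- 2 * pi * (p - 1) / n_points
    dy <- -radius * sin(a)      # y axis points down; standard LBP order
    dx <- radius * cos(a)
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0; fx <- dx - x0
    # snap near-integer offsets so exact neighbours are sampled exactly
    if (abs(fy) < 1e-9) fy <- 0
    if (abs(fx) < 1e-9) fx <- 0
    if (abs(fy - 1) < 1e-9) { fy <- 0; y0 <- y0 + 1 }
    if (abs(fx - 1) < 1e-9) { fx <- 0; x0 <- x0 + 1 }
    sub <- function(oy, ox) img[ri + y0 + oy, ci + x0 + ox, drop = FALSE]
    # only touch the neighbours with non-zero weight (an exact-integer
    # offset would otherwise index one pixel beyond the margin)
    nb <- (1 - fy) * (1 - fx) * sub(0, 0)
    if (fx > 0) nb <- nb + (1 - fy) * fx * sub(0, 1)
    if (fy > 0) nb <- nb + fy * (1 - fx) * sub(1, 0)
    if (fx > 0 && fy > 0) nb <- nb + fy * fx * sub(1, 1)
    bits[, p] <- as.integer(nb >= center)
  }
  trans <- rowSums(bits != bits[, c(2:n_points, 1), drop = FALSE])
  ones <- rowSums(bits)
  bin <- ifelse(trans <= 2, ones, n_points + 1)   # 0..P uniform, P+1 other
  counts <- tabulate(bin + 1L, nbins = n_points + 2L)
  structure(counts / sum(counts), scheme = "LBP")
}

#' Per-channel intensity histograms
#'
#' @param img grayscale matrix (for `"gray"`) or RGB array (for `"RGB"` /
#'   `"HSV"`; requesting a colour histogram on a grayscale input is an
#'   error).
#' @param colorspace `"gray"`, `"HSV"` or `"RGB"`.
#' @param bins histogram bins per channel (>= 2).
#' @return normalized histogram vector: `bins` values for gray, `3 * bins`
#'   for colour; attribute `scheme`.
#' @export
intensity_histograms <- function(img, colorspace = c("gray", "HSV", "RGB"),
                                 bins = 32) {
  colorspace <- match.arg(colorspace)
  stopifnot(bins >= 2)
  hist01 <- function(v) {
    b <- pmin(floor(v * bins) + 1, bins)
    counts <- tabulate(b, nbins = bins)
    counts / sum(counts)
  }
  if (colorspace == "gray") {
    if (is_rgb_image(img)) img <- rgb_to_gray(img)
    assert_gray(img)
    out <- hist01(clip01(as.vector(img)) / 256)
  } else {
    if (!is_rgb_image(img)) {
      stop(colorspace, " histograms need an RGB input", call. = FALSE)
    }
    if (colorspace == "RGB") {
      out <- c(hist01(clip01(as.vector(img[, , 1])) / 256),
               hist01(clip01(as.vector(img[, , 2])) / 256),
               hist01(clip01(as.vector(img[, , 3])) / 256))
    } else {
      hsv <- grDevices::rgb2hsv(r = clip01(as.vector(img[, , 1])),
                                g = clip01(as.vector(img[, , 2])),
                                b = clip01(as.vector(img[, , 3])),
                                maxColorValue = 255)
      out <- c(hist01(pmin(hsv[1, ], 1 - 1e-12)),
               hist01(pmin(hsv[2, ], 1 - 1e-12)),
               hist01(pmin(hsv[3, ], 1 - 1e-12)))
    }
  }
  structure(out, scheme = paste0(colorspace, "_hist"))
}

#' Extract a feature matrix from a patch set
#'
#' @param patches list of patch objects.
#' @param scheme one of `"GLCM"`, `"Gabor"`, `"LBP"`, `"gray_hist"`,
#'   `"HSV_hist"`, `"RGB_hist"`.
#' @param ... scheme parameters forwarded to the extractor.
#' @return numeric matrix, one row per patch.
#' @export
extract_features <- function(patches, scheme, ...) {
  f <- switch(scheme,
              GLCM = function(p) glcm_features(patch_gray(p), ...),
              Gabor = function(p) gabor_features(patch_gray(p), ...),
              LBP = function(p) lbp_histogram(patch_gray(p), ...),
              gray_hist = function(p)
                intensity_histograms(patch_gray(p), "gray", ...),
              HSV_hist = function(p)
                intensity_histograms(patch_rgb(p), "HSV", ...),
              RGB_hist = function(p)
                intensity_histograms(patch_rgb(p), "RGB", ...),
              stop("unknown feature scheme '", scheme, "'", call. = FALSE))
  t(vapply(patches, function(p) as.numeric(f(p)),
           numeric(length(f(patches[[1]])))))
}

patch_gray <- function(p) {
  if (is_rgb_image(p$pixels)) rgb_to_gray(p$pixels) else p$pixels
}

patch_rgb <- function(p) {
  if (is_rgb_image(p$pixels)) p$pixels
  else array(rep(p$pixels, 3), c(dim(p$pixels), 3))
}

#' Random-forest classifier
#'
#' Bagged CART trees with Gini splits and per-node feature subsampling
#' (implemented in compiled code; no random-forest package exists in the
#' supported library set).  Fully seeded: the same data + seed give the
#' same forest.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels character/factor labels (>= 2 classes).
#' @param n_trees number of trees.
#' @param mtry features tried per split (default `floor(sqrt(ncol))`).
#' @param min_node minimum node size to attempt a split.
#' @param seed RNG seed.
#' @return object of class `penyek_rf`.
#' @export
train_rf <- function(features, labels, n_trees = 200, mtry = NULL,
                     min_node = 2, seed = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) {
    stop("random forest needs at least 2 classes", call. = FALSE)
  }
  # put BPH last so P(BPH) is always the final score column
  if (all(c("BPH", "benign") %in% lev)) lev <- c("benign", "BPH")
  y <- match(labels, lev) - 1L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  forest <- cpp_rf_train(features, y, length(lev), as.integer(n_trees),
                         as.integer(mtry), as.integer(min_node),
                         as.integer(seed %% 2147483647))
  structure(list(forest = forest, levels = lev, n_trees = n_trees,
                 mtry = mtry, seed = seed),
            class = "penyek_rf")
}

#' Classify with a trained random forest
#'
#' @param classifier a `penyek_rf`.
#' @param features numeric matrix with the training feature layout.
#' @return list with `labels` (predicted classes) and `scores` (vote
#'   fractions per class; rows sum to 1).
#' @export
classify_rf <- function(classifier, features) {
  stopifnot(inherits(classifier, "penyek_rf"))
  votes <- cpp_rf_predict(classifier$forest, as.matrix(features),
                          length(classifier$levels))
  colnames(votes) <- classifier$levels
  list(labels = classifier$levels[max.col(votes, ties.method = "first")],
       scores = votes)
}
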