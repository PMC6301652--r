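## Binarization front end: grayscale conversion, median filtering, iterative
## two-threshold binarization by between-class-variance maximization,
## morphological cleanup, size filtering, patch extraction and Canny-based
## negative-patch mining.

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luma weights 0.299 R + 0.587 G + 0.114 B, rounded
#' half up to an integer intensity.
#'
#' @param img RGB array (H x W x 3, intensities 0-255).
#' @return grayscale matrix.
#' @export
rgb_to_gray <- function(img) {
  assert_rgb(img)
  round_half_up(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Median filter with edge replication
#'
#' @param img grayscale matrix.
#' @param window odd window side, at least 3.
#' @return filtered grayscale matrix.
#' @export
median_filter <- function(img, window = 3) {
  assert_gray(img)
  if (window %% 2 == 0 || window < 3) {
    stop("median window must be odd and >= 3, got ", window, call. = FALSE)
  }
  cpp_median_filter(img, as.integer(window))
}

## between-class variance machinery on a 0..255 histogram ------------------

## histogram counts over intensities 0..255
hist256 <- function(img) {
  v <- as.integer(round_half_up(clip01(as.vector(img))))
  tabulate(v + 1L, nbins = 256L)
}

## 3-class between-class variance for thresholds (t1, t2), classes
## [0..t1], (t1..t2], (t2..255]
bcv3 <- function(counts, t1, t2) {
  lev <- 0:255
  n <- sum(counts)
  mu <- sum(lev * counts) / n
  cls <- list(1:(t1 + 1), (t1 + 2):(t2 + 1), (t2 + 2):256)
  v <- 0
  for (ix in cls) {
    w <- sum(counts[ix]) / n
    if (w > 0) {
      m <- sum(lev[ix] * counts[ix]) / sum(counts[ix])
      v <- v + w * (m - mu)^2
    }
  }
  v
}

#' Iterative two-threshold estimation by between-class variance
#'
#' Splits the intensity histogram into three classes (dark, mid, bright) by
#' coordinate ascent on the three-class between-class-variance objective:
#' each iteration re-places one threshold at the value maximizing the
#' variance with the other fixed, until neither threshold moves by more
#' than `tol` or `max_iter` is reached.  With the other threshold fixed,
#' the update is the classical two-class optimum on the sub-histogram, so
#' the objective never decreases along an ascent.  The ascent is restarted
#' from the histogram's tercile boundaries and a coarse deterministic
#' quantile grid, and the best stationary pair is returned; the grid makes
#' the returned pair agree with the exhaustive-search optimum in all but
#' pathological cases.
#'
#' @param img grayscale matrix (needs at least 3 distinct intensity levels).
#' @param tol convergence tolerance on threshold movement (intensity units);
#'   the default 0 demands exact stationarity.
#' @param max_iter iteration cap.
#' @return object of class `penyek_thresholds`: list with `t_low`,
#'   `t_high`, `iterations`, `converged` and the attained `variance`.
#' @export
iterative_multithreshold <- function(img, tol = 0, max_iter = 100) {
  assert_gray(img)
  counts <- hist256(img)
  levels_present <- which(counts > 0) - 1L
  if (length(levels_present) < 3) {
    stop("image has fewer than 3 distinct intensity levels; ",
         "use a single-threshold (two-class) split instead", call. = FALSE)
  }
  lev <- 0:255
  n <- sum(counts)
  csum_w <- cumsum(counts)
  csum_s <- cumsum(lev * counts)

  ## sum of w * mu^2 for a two-way split of the sub-histogram (lo..hi] at t:
  ## classes (lo..t] and (t..hi]; returns vector over t in lo..(hi-1)
  ## (t, lo are thresholds, i.e. intensity values; lo = -1 means from 0)
  ## csum_w[i] / csum_s[i] hold counts / level sums over levels 0..i-1,
  ## so "count of values <= t" is csum_w[t + 1].
  best_split <- function(lo, hi) {
    base_w <- if (lo >= 0) csum_w[lo + 1] else 0
    base_s <- if (lo >= 0) csum_s[lo + 1] else 0
    W <- csum_w[hi + 1] - base_w
    S <- csum_s[hi + 1] - base_s
    t <- (lo + 1):(hi - 1)
    w0 <- csum_w[t + 1] - base_w
    s0 <- csum_s[t + 1] - base_s
    w1 <- W - w0
    s1 <- S - s0
    obj <- rep(-Inf, length(t))
    ok <- w0 > 0 & w1 > 0
    obj[ok] <- (s0^2 / w0 + s1^2 / w1)[ok]
    t[which.max(obj)]
  }

  quant_level <- function(p) lev[which(csum_w >= p * n)[1]]
  clamp_pair <- function(t1, t2) {
    t1 <- max(min(t1, 253), levels_present[1])
    c(t1, min(max(t2, t1 + 1), 254))
  }

  ascend <- function(t_low, t_high) {
    converged <- FALSE
    iter <- 0
    while (iter < max_iter) {
      iter <- iter + 1
      new_low <- best_split(-1, t_high)
      new_high <- best_split(new_low, 255)
      if (abs(new_low - t_low) <= tol && abs(new_high - t_high) <= tol) {
        t_low <- new_low
        t_high <- new_high
        converged <- TRUE
        break
      }
      t_low <- new_low
      t_high <- new_high
    }
    list(t_low = t_low, t_high = t_high, iterations = iter,
         converged = converged, variance = bcv3(counts, t_low, t_high))
  }

  ## deterministic multi-start: tercile boundaries plus a coarse quantile
  ## grid; each start is a cheap coordinate ascent and the best stationary
  ## pair wins (single-start ascent gets trapped in local optima on flat
  ## histograms more often than the optimality contract tolerates)
  qs <- list(c(1 / 3, 2 / 3))
  grid <- c(0.1, 0.25, 0.4, 0.5, 0.6, 0.75, 0.9)
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (i < j) qs[[length(qs) + 1]] <- c(grid[i], grid[j])
    }
  }
  init0 <- clamp_pair(quant_level(1 / 3), quant_level(2 / 3))
  v0 <- bcv3(counts, init0[1], init0[2])
  best <- NULL
  for (q in qs) {
    tt <- clamp_pair(quant_level(q[1]), quant_level(q[2]))
    res <- ascend(tt[1], tt[2])
    if (is.null(best) || res$variance > best$variance + 1e-12) best <- res
  }
  structure(list(t_low = as.integer(best$t_low),
                 t_high = as.integer(best$t_high),
                 iterations = best$iterations, converged = best$converged,
                 variance = best$variance, variance_init = v0),
            class = "penyek_thresholds")
}

#' Binarize a grayscale image given two thresholds
#'
#' The three histogram classes are `[0, t_low]`, `(t_low, t_high]` and
#' `(t_high, 255]`.  The default rule `"darkest"` marks the dark class as
#' foreground (insects are darker than the pale pad); `"middle"` and
#' `"brightest"` select the other classes.
#'
#' @param img grayscale matrix.
#' @param thr a `penyek_thresholds` object (or list with `t_low`,
#'   `t_high`).
#' @param foreground_rule which class becomes foreground.
#' @return logical mask.
#' @export
binarize <- function(img, thr,
                     foreground_rule = c("darkest", "middle", "brightest")) {
  assert_gray(img)
  rule <- match.arg(foreground_rule)
  switch(rule,
         darkest = img <= thr$t_low,
         middle = img > thr$t_low & img <= thr$t_high,
         brightest = img > thr$t_high)
}

#' Morphological closing followed by opening with a disk element
#'
#' Closing (dilate, then erode) removes holes smaller than the element;
#' opening (erode, then dilate) removes protrusions and specks thinner than
#' it.
#'
#' @param mask logical mask.
#' @param radius disk radius in pixels (>= 1).
#' @return cleaned logical mask.
#' @export
morph_close_open <- function(mask, radius = 1) {
  stopifnot(radius >= 1)
  se <- disk_offsets(radius)
  closed <- erode_mask(dilate_mask(as_mask(mask), se), se)
  dilate_mask(erode_mask(closed, se), se)
}

#' Remove connected components smaller than a minimum area
#'
#' @param mask logical mask.
#' @param min_area components with fewer foreground pixels are deleted.
#' @param connectivity 4 or 8.
#' @return filtered logical mask (always a subset of the input).
#' @export
size_filter <- function(mask, min_area = 30, connectivity = 8) {
  stopifnot(min_area >= 0)
  mask <- as_mask(mask)
  if (min_area == 0 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Run the full binarization chain on a grayscale patch
#'
#' Median filter, iterative two-threshold split (falling back to a
#' two-class split when the patch has fewer than three distinct levels),
#' morphological closing/opening and size filtering.
#'
#' @param img grayscale matrix.
#' @param median_window odd median window.
#' @param foreground_rule passed to [binarize()].
#' @param morph_radius disk radius for cleanup.
#' @param min_area minimum component area.
#' @param connectivity component connectivity.
#' @return logical foreground mask.
#' @export
binarize_chain <- function(img, median_window = 3,
                           foreground_rule = "darkest", morph_radius = 1,
                           min_area = 30, connectivity = 8) {
  sm <- median_filter(img, median_window)
  thr <- tryCatch(iterative_multithreshold(sm), error = function(e) NULL)
  if (is.null(thr)) {
    t1 <- single_threshold(sm)
    thr <- list(t_low = t1, t_high = min(t1 + 1L, 255L))
    if (foreground_rule == "middle") foreground_rule <- "darkest"
  }
  mask <- binarize(sm, thr, foreground_rule)
  mask <- morph_close_open(mask, morph_radius)
  size_filter(mask, min_area, connectivity)
}

## classical two-class between-class-variance threshold (fallback when the
## histogram has fewer than three distinct levels)
single_threshold <- function(img) {
  counts <- hist256(img)
  lev <- 0:255
  w <- cumsum(counts)
  s <- cumsum(lev * counts)
  n <- w[256]; S <- s[256]
  t <- 0:254
  w0 <- w[t + 1]; s0 <- s[t + 1]
  w1 <- n - w0; s1 <- S - s0
  obj <- rep(-Inf, 255)
  ok <- w0 > 0 & w1 > 0
  obj[ok] <- (s0^2 / w0 + s1^2 / w1)[ok]
  as.integer(t[which.max(obj)])
}

#' Extract a square patch around an annotation circle
#'
#' Crops the axis-aligned square of side `2 * radius` centred on the
#' annotation and resizes it to `out_size` by bilinear interpolation.  A
#' circle touching the image border is clamped and edge-padded; this is
#' flagged in the patch's `source$padded`.
#'
#' @param img RGB array or grayscale matrix.
#' @param ann one annotation: list or single-row data frame with
#'   `image_id`, `center_row`, `center_col`, `radius`, `label` (0-based
#'   coordinates).
#' @param out_size output side in pixels.
#' @return a patch object: list with `pixels`, `label`, `size`, `source`.
#' @export
extract_patch <- function(img, ann, out_size = 21) {
  r <- as.numeric(ann$radius)
  stopifnot(r > 0, out_size >= 2)
  h <- dim(img)[1]; w <- dim(img)[2]
  side <- max(2L, as.integer(round(2 * r)))
  # 0-based first row/col of the crop
  r0 <- as.integer(round(ann$center_row - r + 1))
  c0 <- as.integer(round(ann$center_col - r + 1))
  rows <- r0 + 0:(side - 1)
  cols <- c0 + 0:(side - 1)
  padded <- any(rows < 0) || any(rows > h - 1) ||
    any(cols < 0) || any(cols > w - 1)
  rows <- pmin(pmax(rows, 0), h - 1) + 1
  cols <- pmin(pmax(cols, 0), w - 1) + 1
  crop <- if (is_rgb_image(img)) img[rows, cols, , drop = FALSE]
          else img[rows, cols, drop = FALSE]
  pixels <- bilinear_resize(crop, out_size, out_size)
  structure(list(pixels = pixels,
                 label = as.character(ann$label),
                 size = out_size,
                 source = list(image_id = as.character(ann$image_id),
                               index = ann$index %||% NA_integer_,
                               padded = padded)),
            class = "penyek_patch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression quantized to
#' four directions, and two-threshold hysteresis.
#'
#' @param img grayscale matrix.
#' @param lo,hi hysteresis thresholds on gradient magnitude (0-255 scale),
#'   `lo < hi`.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @return logical edge mask.
#' @export
canny_edges <- function(img, lo = 50, hi = 150, sigma = 1) {
  assert_gray(img)
  if (!(lo < hi)) stop("canny thresholds must satisfy lo < hi", call. = FALSE)
  k <- gaussian_kernel(sigma)
  sm <- cpp_conv2_same(img, k, 1L)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)     # d/dcol
  sy <- t(sx)                                             # d/drow
  gx <- cpp_conv2_same(sm, sx, 1L)
  gy <- cpp_conv2_same(sm, sy, 1L)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                                    # -pi..pi
  sector <- (round_half_up(4 * ang / pi) %% 4)            # 0,1,2,3
  h <- nrow(img); w <- ncol(img)
  shift <- function(m, dr, dc) {
    out <- matrix(0, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    okr <- rs >= 1 & rs <= h; okc <- cs >= 1 & cs <= w
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  nms <- matrix(FALSE, h, w)
  dirs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- dirs[[as.character(s)]]
    n1 <- shift(mag, d[1], d[2])
    n2 <- shift(mag, -d[1], -d[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  cand <- nms & mag >= lo
  if (!any(cand)) return(matrix(FALSE, h, w))
  lab <- label_components(cand, 8)
  strong <- unique(lab[cand & mag >= hi])
  strong <- strong[strong > 0]
  matrix(lab %in% strong, h, w)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

#' Mine negative (benign) patches with the Canny edge detector
#'
#' Slides windows over the image, keeps windows whose edge-pixel fraction
#' reaches `min_edge_density` and whose area does not intersect any
#' annotated planthopper circle, and samples up to `max_patches` of them
#' with the given seed.  All returned patches are labelled benign.
#'
#' @param img grayscale matrix.
#' @param annotations annotation data frame (only rows with label `"BPH"`
#'   define exclusion zones).
#' @param canny_lo,canny_hi hysteresis thresholds, `canny_lo < canny_hi`.
#' @param patch_size window side in pixels.
#' @param max_patches cap on the number of returned patches.
#' @param min_edge_density minimum edge-pixel fraction per window.
#' @param seed RNG seed for the sampling step.
#' @param image_id id recorded in the patch source.
#' @return list of benign-labelled patch objects (possibly empty).
#' @export
mine_negative_patches <- function(img, annotations, canny_lo = 50,
                                  canny_hi = 150, patch_size = 21,
                                  max_patches = 20,
                                  min_edge_density = 0.02, seed = 1,
                                  image_id = "image") {
  edges <- canny_edges(img, canny_lo, canny_hi)
  h <- nrow(img); w <- ncol(img)
  if (patch_size > h || patch_size > w) return(list())
  stride <- max(1L, patch_size %/% 2L)
  r0s <- unique(c(seq(0L, h - patch_size, by = stride)))
  c0s <- unique(c(seq(0L, w - patch_size, by = stride)))
  # integral image of the edge mask for O(1) window sums
  cs <- apply(edges * 1, 2, cumsum)
  ii <- rbind(0, cbind(0, t(apply(cs, 1, cumsum))))
  win_sum <- function(r0, c0) {
    ii[r0 + patch_size + 1, c0 + patch_size + 1] -
      ii[r0 + 1, c0 + patch_size + 1] -
      ii[r0 + patch_size + 1, c0 + 1] + ii[r0 + 1, c0 + 1]
  }
  bph <- annotations[annotations$label == "BPH", , drop = FALSE]
  keep <- list()
  for (r0 in r0s) {
    for (c0 in c0s) {
      dens <- win_sum(r0, c0) / patch_size^2
      if (dens < min_edge_density) next
      if (nrow(bph)) {
        # circle vs axis-aligned square intersection test
        cx <- pmin(pmax(bph$center_col, c0), c0 + patch_size - 1)
        cy <- pmin(pmax(bph$center_row, r0), r0 + patch_size - 1)
        d2 <- (cx - bph$center_col)^2 + (cy - bph$center_row)^2
        if (any(d2 <= bph$radius^2)) next
      }
      keep[[length(keep) + 1]] <- c(r0, c0)
    }
  }
  if (!length(keep)) return(list())
  pick <- with_seed(seed, sample(length(keep), min(max_patches, length(keep))))
  lapply(pick, function(i) {
    r0 <- keep[[i]][1]; c0 <- keep[[i]][2]
    structure(list(
      pixels = img[r0 + 1:patch_size, c0 + 1:patch_size, drop = FALSE],
      label = "benign", size = patch_size,
      source = list(image_id = image_id, index = "mined", padded = FALSE,
                    center_row = r0 + (patch_size - 1) / 2,
                    center_col = c0 + (patch_size - 1) / 2)),
      class = "penyek_patch")
  })
}
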