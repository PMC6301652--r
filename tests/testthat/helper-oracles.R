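# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (brute force / direct definitions) and never share code
# with the package internals they verify.

# exact distance transform by minimizing over all background pixels
brute_edt <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# median filter by explicit sort-and-pick-middle (interior pixels only)
brute_median_interior <- function(img, window) {
  r <- window %/% 2
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (i in (r + 1):(h - r)) {
    for (j in (r + 1):(w - r)) {
      v <- sort(as.vector(img[(i - r):(i + r), (j - r):(j + r)]))
      out[i, j] <- v[(length(v) + 1) %/% 2]
    }
  }
  out
}

# three-class between-class-variance objective, shared form used by both
# oracle computations below (sum of s^2/w per class, constant offset aside)
otsu3_objective <- function(img, t1, t2) {
  counts <- tabulate(as.integer(img) + 1L, 256)
  lev <- 0:255
  cw <- cumsum(counts); cs <- cumsum(lev * counts)
  n <- cw[256]
  w0 <- cw[t1 + 1]; s0 <- cs[t1 + 1]
  w1 <- cw[t2 + 1] - w0; s1 <- cs[t2 + 1] - s0
  w2 <- n - cw[t2 + 1]; s2 <- cs[256] - cs[t2 + 1]
  s0^2 / max(w0, 1) + s1^2 / max(w1, 1) + s2^2 / max(w2, 1)
}

# exhaustive search over every threshold pair
exhaustive_otsu3 <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, 256)
  lev <- 0:255
  cw <- cumsum(counts); cs <- cumsum(lev * counts)
  n <- cw[256]
  t1 <- rep(0:253, times = 254 - (0:253))
  t2 <- unlist(lapply(0:253, function(a) (a + 1):254))
  w0 <- cw[t1 + 1]; s0 <- cs[t1 + 1]
  w1 <- cw[t2 + 1] - w0; s1 <- cs[t2 + 1] - s0
  w2 <- n - cw[t2 + 1]; s2 <- cs[256] - cs[t2 + 1]
  v <- ifelse(w0 > 0 & w1 > 0 & w2 > 0,
              s0^2 / pmax(w0, 1) + s1^2 / pmax(w1, 1) + s2^2 / pmax(w2, 1),
              -Inf)
  max(v)
}

# connected-component count by explicit breadth-first flood fill
count_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  n <- 0
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      pi <- (p - 1) %% h + 1; pj <- (p - 1) %/% h + 1
      for (k in seq_along(dr)) {
        ii <- pi + dr[k]; jj <- pj + dc[k]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack <- c(stack, ii + h * (jj - 1))
        }
      }
    }
  }
  n
}

# component areas by flood fill (for the size-filter oracle)
component_areas <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  areas <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    a <- 0L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      a <- a + 1L
      pi <- (p - 1) %% h + 1; pj <- (p - 1) %/% h + 1
      for (k in seq_along(dr)) {
        ii <- pi + dr[k]; jj <- pj + dc[k]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack <- c(stack, ii + h * (jj - 1))
        }
      }
    }
    areas <- c(areas, a)
  }
  areas
}

# trapezoidal ROC integration (second AUC route)
auc_trapezoid <- function(scores, truth, positive = "BPH") {
  pos <- truth == positive
  ths <- sort(unique(scores))
  pts <- rbind(c(1, 1),
               t(vapply(ths, function(t) {
                 pred <- scores > t
                 c(sum(pred & !pos) / sum(!pos), sum(pred & pos) / sum(pos))
               }, numeric(2))))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  pts <- rbind(c(0, 0), pts)
  sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
}

# foreground aspect ratio from second moments (trivial shape feature)
aspect_from_moments <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) < 5) return(NA_real_)
  ev <- eigen(cov(sweep(fg, 2, colMeans(fg))))$values
  sqrt(max(ev) / max(min(ev), 1e-9))
}

random_mask <- function(h, w, p = 0.5) matrix(runif(h * w) < p, h, w)

# random blobby mask (a few dilated seed points); friendlier to skeleton /
# watershed semantics than i.i.d. noise
random_blob_mask <- function(h, w, n_seeds = 4, radius = 3) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_seeds)) {
    cy <- sample(seq_len(h), 1); cx <- sample(seq_len(w), 1)
    rr <- pmax(1, cy - radius):pmin(h, cy + radius)
    cc <- pmax(1, cx - radius):pmin(w, cx + radius)
    sub <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2 <= radius^2)
    m[rr, cc] <- m[rr, cc] | sub
  }
  m
}

disk_mask <- function(h, w, cy, cx, r) {
  row <- matrix(rep(1:h, w), h, w)
  col <- matrix(rep(1:w, each = h), h, w)
  (row - cy)^2 + (col - cx)^2 <= r^2
}
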