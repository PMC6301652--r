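## Raster containers and small geometry helpers shared by all stages.
##
## Conventions (used everywhere in the package):
##   * GrayImage  -- numeric matrix, intensities in [0, 255]
##   * RGBImage   -- numeric H x W x 3 array, intensities in [0, 255]
##   * BinaryMask -- logical matrix, TRUE = foreground
##   * coordinates are 0-based, row-major, origin at the top-left corner
##     (row = y from top), including in annotation CSV files.

#' Round half away from zero ("round half up" for non-negative input)
#'
#' Intensity quantization throughout the package uses this rule rather than
#' R's banker's rounding, so that e.g. 76.245 * luma arithmetic and distance
#' map rescaling behave like conventional image libraries.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

is_gray_image <- function(img) is.matrix(img) && is.numeric(img)

assert_rgb <- function(img) {
  if (!is_rgb_image(img)) {
    stop("expected an RGB image (H x W x 3 array), got ",
         paste(class(img), collapse = "/"), call. = FALSE)
  }
  invisible(img)
}

assert_gray <- function(img) {
  if (!is_gray_image(img)) {
    stop("expected a grayscale image (numeric matrix)", call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask)) stop("expected a binary mask (logical matrix)",
                             call. = FALSE)
  invisible(mask)
}

as_mask <- function(mask) {
  assert_mask(mask)
  storage.mode(mask) <- "logical"
  mask
}

int_mask <- function(mask) {
  m <- as_mask(mask)
  storage.mode(m) <- "integer"
  m
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream; seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

## structuring-element offsets --------------------------------------------

## rasterized disk with half-pixel inflation (radius 1 is the 3x3 box, so
## that axis-aligned rectangles are fixed points of closing/opening)
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= (radius + 0.5)^2
  as.matrix(g[keep, , drop = FALSE])
}

cross_offsets <- function() {
  matrix(c(0L, 0L, -1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L),
         ncol = 2, byrow = TRUE)
}

erode_mask <- function(mask, offsets) {
  out <- cpp_binary_morph(int_mask(mask), offsets, FALSE)
  storage.mode(out) <- "logical"
  out
}

dilate_mask <- function(mask, offsets) {
  out <- cpp_binary_morph(int_mask(mask), offsets, TRUE)
  storage.mode(out) <- "logical"
  out
}

label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  cpp_label_components(int_mask(mask), as.integer(connectivity))
}

## geometry ---------------------------------------------------------------

#' Resize an image by bilinear interpolation
#'
#' Output pixel centres are mapped back into the source grid; source
#' coordinates are clamped at the borders (edge replication).  When input
#' and output sizes are equal the pixels are returned untouched.
#'
#' @param img grayscale matrix or RGB array.
#' @param out_h,out_w output size in pixels.
#' @return resized image of the same kind as the input.
#' @export
bilinear_resize <- function(img, out_h, out_w = out_h) {
  if (is_rgb_image(img)) {
    out <- array(0, c(out_h, out_w, 3))
    for (c in 1:3) out[, , c] <- bilinear_resize(img[, , c], out_h, out_w)
    return(out)
  }
  assert_gray(img)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  sy <- h / out_h; sx <- w / out_w
  yi <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), h - 1)
  xi <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), w - 1)
  y0 <- pmin(floor(yi), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(xi), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- yi - y0; fx <- xi - x0
  a <- img[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- img[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
  d <- img[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
  e <- img[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  a + b + d + e
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Rotate an image about its centre
#'
#' Multiples of 90 degrees are executed as exact index permutations (so four
#' successive 90-degree turns restore the input bit-exactly); any other
#' angle uses inverse-mapped bilinear interpolation with edge replication.
#'
#' @param img grayscale matrix or RGB array.
#' @param angle rotation in degrees, counter-clockwise.
#' @return rotated image, same size as the input.
#' @export
rotate_image <- function(img, angle) {
  if (is_rgb_image(img)) {
    out <- array(0, dim(img))
    for (c in 1:3) out[, , c] <- rotate_image(img[, , c], angle)
    return(out)
  }
  assert_gray(img)
  a <- angle %% 360
  if (isTRUE(all.equal(a, 0))) return(img)
  if (nrow(img) == ncol(img)) {
    if (isTRUE(all.equal(a, 90)))  return(rot90_cw(rot90_cw(rot90_cw(img))))
    if (isTRUE(all.equal(a, 180))) return(img[nrow(img):1, ncol(img):1])
    if (isTRUE(all.equal(a, 270))) return(rot90_cw(img))
  }
  h <- nrow(img); w <- ncol(img)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  th <- a * pi / 180
  co <- cos(th); si <- sin(th)
  out_r <- matrix(rep(0:(h - 1), w), h, w)
  out_c <- matrix(rep(0:(w - 1), each = h), h, w)
  dy <- out_r - cy; dx <- out_c - cx
  # inverse rotation into source coordinates
  src_y <- co * dy + si * dx + cy
  src_x <- -si * dy + co * dx + cx
  src_y <- pmin(pmax(src_y, 0), h - 1)
  src_x <- pmin(pmax(src_x, 0), w - 1)
  y0 <- pmin(floor(src_y), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(src_x), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- src_y - y0; fx <- src_x - x0
  idx <- function(r, c) img[cbind(as.vector(r) + 1, as.vector(c) + 1)]
  v <- idx(y0, x0) * (1 - fy) * (1 - fx) + idx(y0, x1) * (1 - fy) * fx +
    idx(y1, x0) * fy * (1 - fx) + idx(y1, x1) * fy * fx
  matrix(v, h, w)
}

#' Translate an image by whole pixels with edge replication
#'
#' @param img grayscale matrix or RGB array.
#' @param dr,dc shift in rows/columns (positive = down/right).
#' @return shifted image, same size.
#' @export
translate_image <- function(img, dr, dc) {
  if (is_rgb_image(img)) {
    out <- array(0, dim(img))
    for (c in 1:3) out[, , c] <- translate_image(img[, , c], dr, dc)
    return(out)
  }
  assert_gray(img)
  h <- nrow(img); w <- ncol(img)
  ri <- pmin(pmax(seq_len(h) - round(dr), 1), h)
  ci <- pmin(pmax(seq_len(w) - round(dc), 1), w)
  img[ri, ci, drop = FALSE]
}

## image file I/O ---------------------------------------------------------

#' Read / write 8-bit images
#'
#' PNG files are handled through the \pkg{png} package; plain-text netpbm
#' files (`.pgm` P2 grayscale, `.ppm` P3 colour) are supported so that small
#' fixtures can live in version control as text.
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`,
#'   `.ppm`).
#' @param img grayscale matrix or RGB array with intensities in [0, 255].
#' @return `read_image()` returns a grayscale matrix or RGB array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] >= 3L) return(px[, , 1:3, drop = TRUE] * 255)
      px <- px[, , 1]
    }
    return(px * 255)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pnm(path))
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- clip01(img) / 255
    png::writePNG(px, path)
  } else if (ext %in% c("pgm", "ppm")) {
    write_pnm(img, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

read_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  nums <- as.numeric(toks[-1])
  w <- nums[1]; h <- nums[2]
  px <- nums[-(1:3)]
  if (magic == "P2") {
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P3") {
    arr <- array(0, c(h, w, 3))
    m <- matrix(px, ncol = 3, byrow = TRUE)   # rows are pixels, row-major
    for (c in 1:3) arr[, , c] <- matrix(m[, c], nrow = h, byrow = TRUE)
    arr
  } else {
    stop("unsupported netpbm magic '", magic, "'", call. = FALSE)
  }
}

write_pnm <- function(img, path) {
  img <- round_half_up(clip01(img))
  con <- file(path, "w")
  on.exit(close(con))
  if (is_rgb_image(img)) {
    writeLines(c("P3", paste(ncol(img), nrow(img)), "255"), con)
    m <- cbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
               as.vector(t(img[, , 3])))
    writeLines(apply(m, 1, paste, collapse = " "), con)
  } else {
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    writeLines(apply(matrix(img, nrow(img), ncol(img)), 1,
                     paste, collapse = " "), con)
  }
  invisible(path)
}
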