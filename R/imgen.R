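## Synthetic sticky-pad scene generator.
##
## The original field imagery (smartphone photographs of glue-coated pads in
## a rice paddy) was never deposited, so this module emulates its stated
## character: a pale cluttered pad with glue specks, uneven illumination, two
## insect classes with distinct morphology (elongated planthoppers vs rounder
## benign insects), and "imperfect" specimens whose bodies are partly torn
## away and sheared by the impact with the pad.  Everything is procedural and
## seeded: the same configuration always yields a bit-identical scene.

#' Scene configuration
#'
#' @param height,width scene size in pixels.
#' @param n_bph,n_benign number of insects of each class to place.
#' @param distortion fraction in [0, 1]: how much of each insect body is
#'   torn away / sheared to emulate damage (0 = intact).
#' @param illum_gradient maximum relative brightness change across the pad,
#'   in [0, 1] (multiplicative linear ramp with a random direction).
#' @param speck_density glue specks per megapixel.
#' @param noise_sd additive Gaussian intensity noise, 0-255 scale.
#' @param seed RNG seed; identical config + seed gives an identical scene.
#' @return object of class `penyek_scene_config`.
#' @export
scene_config <- function(height = 512, width = 512, n_bph = 5, n_benign = 5,
                         distortion = 0.5, illum_gradient = 0.2,
                         speck_density = 50, noise_sd = 5, seed = 1) {
  stopifnot(height >= 32, width >= 32, n_bph >= 0, n_benign >= 0,
            distortion >= 0, distortion <= 1,
            illum_gradient >= 0, illum_gradient <= 1,
            speck_density >= 0, noise_sd >= 0)
  structure(list(height = height, width = width, n_bph = n_bph,
                 n_benign = n_benign, distortion = distortion,
                 illum_gradient = illum_gradient,
                 speck_density = speck_density, noise_sd = noise_sd,
                 seed = seed),
            class = "penyek_scene_config")
}

## ellipse mask on an n x n canvas; orientation in radians
ellipse_mask <- function(n, a, b, theta = 0, cy = (n - 1) / 2,
                         cx = (n - 1) / 2) {
  r <- matrix(rep(0:(n - 1), n), n, n) - cy
  c <- matrix(rep(0:(n - 1), each = n), n, n) - cx
  u <- cos(theta) * c + sin(theta) * r
  v <- -sin(theta) * c + cos(theta) * r
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a single insect sprite
#'
#' Planthopper (`"BPH"`) sprites are elongated ellipsoids with a narrow head
#' and two wing lobes; `"benign"` sprites are rounder with a ring of short
#' appendages, so the two classes stay separable by simple shape statistics.
#' Damage is emulated by deleting a random angular sector of the body
#' (target area about `distortion * 30%` of the sprite) followed by a random
#' affine shear whose magnitude also scales with `distortion`.
#'
#' @param class_label `"BPH"` or `"benign"`.
#' @param distortion damage fraction in [0, 1].
#' @param seed optional RNG seed (NULL = use the current RNG stream).
#' @param size sprite canvas side in pixels.
#' @return list with `gray` (intensity matrix), `mask` (logical alpha) and
#'   `label`.
#' @export
render_insect <- function(class_label, distortion = 0, seed = NULL,
                          size = 48) {
  if (!class_label %in% c("BPH", "benign")) {
    stop("unknown insect class '", class_label,
         "'; expected \"BPH\" or \"benign\"", call. = FALSE)
  }
  stopifnot(distortion >= 0, distortion <= 1)
  with_seed(seed, {
    n <- size
    cy <- (n - 1) / 2
    cx <- (n - 1) / 2
    if (class_label == "BPH") {
      a <- runif(1, 0.30, 0.36) * n            # major semi-axis
      b <- a / runif(1, 2.6, 3.1)              # aspect ratio 2.6-3.1
      body <- ellipse_mask(n, a, b)
      # narrow head capsule at one end
      head <- ellipse_mask(n, 0.28 * b, 0.5 * b, 0, cy, cx + a * 0.95)
      # two wing lobes along the back
      lob1 <- ellipse_mask(n, 0.55 * a, 0.55 * b, 0.12, cy - 0.7 * b,
                           cx - 0.25 * a)
      lob2 <- ellipse_mask(n, 0.55 * a, 0.55 * b, -0.12, cy + 0.7 * b,
                           cx - 0.25 * a)
      mask <- body | head | lob1 | lob2
      base_int <- runif(1, 60, 85)
    } else {
      a <- runif(1, 0.21, 0.25) * n
      b <- a / runif(1, 1.1, 1.35)             # aspect ratio 1.1-1.35
      mask <- ellipse_mask(n, a, b)
      # ring of short appendages
      k <- sample(5:7, 1)
      ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] + runif(1, 0, pi)
      for (t in ang) {
        mask <- mask | ellipse_mask(n, 0.16 * a, 0.16 * a, 0,
                                    cy + (b + 0.1 * a) * sin(t),
                                    cx + (a + 0.1 * a) * cos(t))
      }
      base_int <- runif(1, 55, 80)
    }

    if (distortion > 0) {
      mask <- distort_sprite(mask, distortion)
    }

    # shading: slightly darker core, mild texture; kept flat enough that
    # the insect forms a single dark histogram class against the pale pad
    gray <- matrix(0, n, n)
    if (any(mask)) {
      edm <- cpp_edt(int_mask(mask))
      depth <- edm / max(edm, 1)
      gray <- (base_int - 3 * depth) + matrix(rnorm(n * n, 0, 1.5), n, n)
      gray <- clip01(gray)
    }
    gray[!mask] <- 0
    list(gray = gray, mask = mask, label = class_label)
  })
}

## tear out a random boundary sector (~distortion * 30% of the area) and
## apply a random shear proportional to distortion
distort_sprite <- function(mask, distortion) {
  n <- nrow(mask)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(mask)
  cy <- mean(fg[, 1]); cx <- mean(fg[, 2])
  ang <- atan2(fg[, 1] - cy, fg[, 2] - cx)
  target <- distortion * 0.30 * nrow(fg)
  theta0 <- runif(1, -pi, pi)
  # widen the angular window until enough area is removed
  d <- (ang - theta0) %% (2 * pi)
  ord <- order(d)
  take <- ord[seq_len(min(nrow(fg), max(0, round(target))))]
  if (length(take)) mask[fg[take, , drop = FALSE]] <- FALSE

  sh <- distortion * runif(1, -0.35, 0.35)
  if (abs(sh) > 1e-3) {
    # inverse-mapped shear about the centroid, nearest neighbour
    out <- matrix(FALSE, n, n)
    oc <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
    sy <- oc[, 1]
    sx <- (oc[, 2] - cx) - sh * (oc[, 1] - cy) + cx
    sx <- round(sx); ok <- sx >= 1 & sx <= n
    out[oc[ok, , drop = FALSE]] <- mask[cbind(sy[ok], sx[ok])]
    mask <- out
  }
  mask
}

#' Generate a full synthetic sticky-pad scene
#'
#' Places the requested insects without overlap (bounded retries), adds glue
#' specks, a multiplicative linear illumination ramp with random direction,
#' and additive Gaussian noise.  Each placed insect is annotated with the
#' smallest bounding circle that covers all of its foreground pixels.
#'
#' @param cfg a [scene_config()].
#' @return list with `image` (RGB array) and `truth` (data frame with
#'   columns `image_id`, `center_row`, `center_col`, `radius`, `label`;
#'   0-based pixel coordinates), plus the config as an attribute.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "penyek_scene_config"))
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    pad <- matrix(205 + rnorm(h * w, 0, 2), h, w)

    labels <- c(rep("BPH", cfg$n_bph), rep("benign", cfg$n_benign))
    ann <- list()
    placed <- NULL   # matrix: center_row, center_col, radius (0-based)
    scene_rgb <- array(0, c(h, w, 3))
    # per-insect colour: planthoppers trend brown, benign insects trend
    # grey-green, but the distributions overlap (colour alone should be
    # informative, not decisive)
    draw_tint <- function(label) {
      if (label == "BPH") c(1.00, runif(1, 0.80, 1.00), runif(1, 0.60, 0.95))
      else c(runif(1, 0.97, 1.00), runif(1, 0.83, 1.00), runif(1, 0.65, 0.95))
    }
    sprites <- list()
    for (i in seq_along(labels)) {
      spr <- render_insect(labels[i], cfg$distortion)
      if (!any(spr$mask)) spr <- render_insect(labels[i], 0)
      fg <- which(spr$mask, arr.ind = TRUE)
      scy <- mean(range(fg[, 1])); scx <- mean(range(fg[, 2]))
      rad <- ceiling(sqrt(max((fg[, 1] - scy)^2 + (fg[, 2] - scx)^2))) + 1
      ok <- FALSE
      for (try in 1:200) {
        cr <- runif(1, rad + 1, h - rad - 2)
        cc <- runif(1, rad + 1, w - rad - 2)
        if (is.null(placed) ||
            all(sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2) >
                placed[, 3] + rad + 2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place insect ", i, " of ", length(labels),
             " without overlap after 200 retries; reduce counts or ",
             "enlarge the scene", call. = FALSE)
      }
      placed <- rbind(placed, c(cr, cc, rad))
      sprites[[i]] <- list(spr = spr, cr = cr, cc = cc,
                           scy = scy, scx = scx)
      ann[[i]] <- data.frame(center_row = round(cr), center_col = round(cc),
                             radius = rad, label = labels[i],
                             stringsAsFactors = FALSE)
    }

    # glue specks: small translucent dots
    n_speck <- round(cfg$speck_density * h * w / 1e6)
    if (n_speck > 0) {
      sr <- runif(n_speck, 2, h - 3)
      sc <- runif(n_speck, 2, w - 3)
      srad <- sample(1:2, n_speck, replace = TRUE)
      sint <- runif(n_speck, -45, 25)
      for (s in seq_len(n_speck)) {
        rr <- max(1, round(sr[s]) - srad[s]):min(h, round(sr[s]) + srad[s])
        cc2 <- max(1, round(sc[s]) - srad[s]):min(w, round(sc[s]) + srad[s])
        pad[rr, cc2] <- pad[rr, cc2] + sint[s]
      }
    }

    for (c in 1:3) scene_rgb[, , c] <- pad

    # stamp insects (per-class colour tint over the sprite intensity)
    for (sp in sprites) {
      spr <- sp$spr
      fg <- which(spr$mask, arr.ind = TRUE)
      rr <- round(sp$cr) + fg[, 1] - round(sp$scy)
      cc2 <- round(sp$cc) + fg[, 2] - round(sp$scx)
      keep <- rr >= 1 & rr <= h & cc2 >= 1 & cc2 <= w
      tt <- draw_tint(spr$label)
      for (c in 1:3) {
        scene_rgb[, , c][cbind(rr[keep], cc2[keep])] <-
          spr$gray[fg[keep, , drop = FALSE]] * tt[c]
      }
    }

    # multiplicative illumination ramp with random direction
    if (cfg$illum_gradient > 0) {
      phi <- runif(1, 0, 2 * pi)
      r <- matrix(rep(0:(h - 1), w), h, w) / max(h - 1, 1)
      c2 <- matrix(rep(0:(w - 1), each = h), h, w) / max(w - 1, 1)
      proj <- cos(phi) * c2 + sin(phi) * r
      proj <- (proj - min(proj)) / max(max(proj) - min(proj), 1e-12)
      ramp <- 1 - cfg$illum_gradient / 2 + cfg$illum_gradient * proj
      for (c in 1:3) scene_rgb[, , c] <- scene_rgb[, , c] * ramp
    }

    if (cfg$noise_sd > 0) {
      for (c in 1:3) {
        scene_rgb[, , c] <- scene_rgb[, , c] + rnorm(h * w, 0, cfg$noise_sd)
      }
    }
    scene_rgb <- clip01(scene_rgb)

    truth <- if (length(ann)) {
      cbind(data.frame(image_id = "scene", stringsAsFactors = FALSE),
            do.call(rbind, ann))
    } else {
      data.frame(image_id = character(), center_row = numeric(),
                 center_col = numeric(), radius = numeric(),
                 label = character(), stringsAsFactors = FALSE)
    }
    # 0-based coordinates in the annotation contract
    if (nrow(truth)) {
      truth$center_row <- truth$center_row - 1
      truth$center_col <- truth$center_col - 1
    }
    structure(list(image = scene_rgb, truth = truth), config = cfg,
              class = "penyek_scene")
  })
}

#' Largest-remainder split of `n` items into integer parts
#'
#' @param n total count.
#' @param fracs fractions summing to 1.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(n, fracs) {
  stopifnot(abs(sum(fracs) - 1) <= 1e-9)
  raw <- n * fracs
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Generate a labelled patch set
#'
#' Renders `n_bph + n_benign` single-insect mini-scenes (one scene per
#' patch, each with its own scene id) and crops the annotated patch from
#' each.  This is the raw material for [generate_dataset()] and for the
#' cross-validated experiments.
#'
#' @param n_bph,n_benign patches per class.
#' @param distortion damage fraction passed to the sprite renderer.
#' @param patch_size output patch side in pixels.
#' @param seed RNG seed.
#' @param scene_size side of each mini-scene.
#' @param noise_sd,illum_gradient,speck_density scene nuisance parameters.
#' @return list of patch objects (`pixels` RGB array, `label`, `source`).
#' @export
make_patch_set <- function(n_bph, n_benign, distortion = 0.5,
                           patch_size = 21, seed = 1, scene_size = 64,
                           noise_sd = 5, illum_gradient = 0.2,
                           speck_density = 50) {
  labels <- c(rep("BPH", n_bph), rep("benign", n_benign))
  patches <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cfg <- scene_config(height = scene_size, width = scene_size,
                        n_bph = as.integer(labels[i] == "BPH"),
                        n_benign = as.integer(labels[i] == "benign"),
                        distortion = distortion,
                        illum_gradient = illum_gradient,
                        speck_density = speck_density,
                        noise_sd = noise_sd,
                        seed = (seed * 100003 + i) %% 2147483647)
    sc <- generate_scene(cfg)
    ann <- sc$truth[1, ]
    ann$image_id <- sprintf("scene_%05d", i)
    p <- extract_patch(sc$image, ann, patch_size)
    p$source$index <- i
    patches[[i]] <- p
  }
  patches
}

#' Generate a stratified, leakage-free train/validation/test dataset
#'
#' The default split fractions (70/10/20) reproduce the published per-class
#' split sizes at the published dataset sizes: 337 planthopper patches give
#' 236/34/67 and 350 benign patches give 245/35/70, by largest-remainder
#' rounding per class.  Splitting is by scene id, so no scene contributes to
#' more than one split.
#'
#' @param n_bph,n_benign patches per class.
#' @param split train/validation/test fractions, summing to 1.
#' @param patch_size patch side in pixels.
#' @param distortion,scene_size,noise_sd,illum_gradient,speck_density
#'   passed to [make_patch_set()].
#' @param seed RNG seed controlling rendering and split membership.
#' @return object of class `penyek_dataset`: list with `train`, `val`,
#'   `test` (lists of patches) and a `manifest` data frame.
#' @export
generate_dataset <- function(n_bph = 337, n_benign = 350,
                             split = c(0.7, 0.1, 0.2), patch_size = 21,
                             distortion = 0.5, seed = 1, scene_size = 64,
                             noise_sd = 5, illum_gradient = 0.2,
                             speck_density = 50) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) <= 1e-9)
  patches <- make_patch_set(n_bph, n_benign, distortion = distortion,
                            patch_size = patch_size, seed = seed,
                            scene_size = scene_size, noise_sd = noise_sd,
                            illum_gradient = illum_gradient,
                            speck_density = speck_density)
  labels <- vapply(patches, `[[`, "", "label")
  out <- list(train = list(), val = list(), test = list())
  rows <- list()
  for (cl in c("BPH", "benign")) {
    idx <- which(labels == cl)
    sizes <- largest_remainder(length(idx), split)
    if (any(sizes == 0)) {
      stop("class '", cl, "' would receive 0 items in some split ",
           "(sizes: ", paste(sizes, collapse = "/"),
           "); increase counts or change fractions", call. = FALSE)
    }
    idx <- with_seed(seed + match(cl, c("BPH", "benign")), sample(idx))
    parts <- rep(c("train", "val", "test"), times = sizes)
    for (k in seq_along(idx)) {
      p <- patches[[idx[k]]]
      out[[parts[k]]] <- c(out[[parts[k]]], list(p))
      rows[[length(rows) + 1]] <- data.frame(
        image_id = p$source$image_id, label = p$label, split = parts[k],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(train = out$train, val = out$val, test = out$test,
                 manifest = do.call(rbind, rows)),
            class = "penyek_dataset")
}

#' Write a scene and its ground truth to disk
#'
#' The image goes out as 8-bit PNG (or plain-text PGM/PPM by extension); the
#' ground truth as a CSV with header
#' `image_id,center_row,center_col,radius,label` in 0-based coordinates.
#'
#' @param scene a `penyek_scene` from [generate_scene()].
#' @param image_path,truth_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_scene <- function(scene, image_path, truth_path) {
  write_image(scene$image, image_path)
  write.csv(scene$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(image_path, truth_path))
}

#' Read a ground-truth annotation CSV
#'
#' @param path CSV with columns `image_id, center_row, center_col, radius,
#'   label` (0-based coordinates).
#' @return data frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "center_row", "center_col", "radius", "label")
  if (!all(need %in% names(ann))) {
    stop("annotation file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ann
}
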