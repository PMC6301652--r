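## The six binary image models applied to binarized patches before
## classification: outline (A), fill holes (B), skeletonize (C), watershed
## separation (D), Voronoi tessellation lines (E), Euclidean distance map
## (F), plus the raw-RGB passthrough (G).  All transforms are deterministic.

#' Inner outline of a mask
#'
#' One-pixel-wide inner boundary: `mask AND NOT erode(mask, 3x3 cross)`.
#'
#' @param mask logical mask.
#' @return logical outline mask (always a subset of the input).
#' @export
outline <- function(mask) {
  mask <- as_mask(mask)
  mask & !erode_mask(mask, cross_offsets())
}

#' Fill enclosed holes in a mask
#'
#' Background components not 4-connected to the image border become
#' foreground; border-connected background is untouched.
#'
#' @param mask logical mask.
#' @return filled logical mask (always a superset of the input).
#' @export
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  lab <- label_components(!mask, 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

#' Skeletonize a mask by iterative thinning
#'
#' Zhang-Suen two-subiteration thinning: the result is a maximally thin,
#' 8-connectivity-preserving skeleton contained in the input.
#'
#' @param mask logical mask.
#' @return logical skeleton mask.
#' @export
skeletonize <- function(mask) {
  out <- cpp_zhang_suen(int_mask(mask))
  storage.mode(out) <- "logical"
  out
}

#' Exact Euclidean distance map
#'
#' Assigns every foreground pixel its exact Euclidean distance to the
#' nearest background pixel (per-dimension lower-envelope algorithm;
#' background pixels carry 0).  A mask with no background pixel is an
#' error: callers guarantee background exists after binarization.
#'
#' @param mask logical mask.
#' @return numeric distance matrix of class `penyek_edm`.
#' @export
euclidean_distance_map <- function(mask) {
  mask <- as_mask(mask)
  if (all(mask)) {
    stop("no background pixel: the Euclidean distance map is undefined ",
         "for an all-foreground mask", call. = FALSE)
  }
  structure(cpp_edt(int_mask(mask)), class = c("penyek_edm", "matrix"))
}

#' Rescale a distance map to an 8-bit grayscale image
#'
#' Linear rescale with 0 mapping to 0 and the per-image maximum distance to
#' 255, rounded half up; an all-zero map stays all zero.
#'
#' @param edm distance matrix from [euclidean_distance_map()].
#' @return grayscale matrix.
#' @export
edm_to_gray <- function(edm) {
  m <- max(edm)
  if (m <= 0) return(matrix(0, nrow(edm), ncol(edm)))
  round_half_up(unclass(edm) / m * 255)
}

#' Watershed separation of touching blobs
#'
#' Classic binary watershed: the distance map of the foreground is flooded
#' downhill from its regional maxima (maxima within `tolerance` of a saddle
#' are merged); pixels where distinct basins meet become ridge pixels and
#' are removed, so touching convex blobs split into separate components.
#'
#' @param mask logical mask.
#' @param tolerance plateau-merging tolerance in distance units.
#' @return logical mask (subset of the input, ridge pixels removed).
#' @export
watershed_binary <- function(mask, tolerance = 0.5) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  if (all(mask)) return(mask)   # no background: nothing to flood against
  edm <- cpp_edt(int_mask(mask))
  out <- cpp_watershed_split(edm, tolerance)
  storage.mode(out) <- "logical"
  out
}

#' Voronoi tessellation lines between mask components
#'
#' Flood the background outward from each particle by increasing distance;
#' the one-pixel ridges where two different particles meet are the Voronoi
#' lines.  With fewer than two components the output is empty.  Lines lie
#' entirely in the background.
#'
#' @param mask logical mask with at least one component.
#' @return logical mask of the tessellation lines.
#' @export
voronoi <- function(mask) {
  mask <- as_mask(mask)
  lab <- label_components(mask, 8)
  if (max(lab) < 2) return(matrix(FALSE, nrow(mask), ncol(mask)))
  bgdist <- cpp_edt(int_mask(!mask))
  out <- cpp_voronoi_lines(lab, bgdist)
  storage.mode(out) <- "logical"
  out
}

#' Image-model table
#'
#' The seven classifier input models: A outline, B fill holes,
#' C skeletonize, D watershed, E Voronoi, F Euclidean distance map (as
#' grayscale), G raw RGB passthrough.  A-E are rendered as 0/255 grayscale.
#'
#' @param patch_mask binarized patch (logical mask); ignored for model G.
#' @param patch_rgb RGB array; required for model G.
#' @param model one of `"A"`..`"G"`.
#' @return grayscale matrix (models A-F) or the RGB array (model G).
#' @export
apply_image_model <- function(patch_mask, patch_rgb = NULL, model) {
  if (!is.character(model) || length(model) != 1 ||
      !model %in% LETTERS[1:7]) {
    stop("unknown image model '", paste(model, collapse = ","),
         "'; expected one of A..G", call. = FALSE)
  }
  if (model == "G") {
    if (is.null(patch_rgb)) stop("model G needs the RGB patch", call. = FALSE)
    return(patch_rgb)
  }
  mask <- as_mask(patch_mask)
  if (model == "F") {
    if (all(mask)) mask[c(1, nrow(mask)), ] <- FALSE  # guarantee background
    return(edm_to_gray(euclidean_distance_map(mask)))
  }
  out <- switch(model,
                A = outline(mask),
                B = fill_holes(mask),
                C = skeletonize(mask),
                D = watershed_binary(mask),
                E = voronoi(mask))
  out * 255
}
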