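# Core label-map representation and geometric preprocessing.
#
# A segmentation mask is an integer matrix over four classes:
#   0 = BG (background), 1 = EL (compacted external layer),
#   2 = IC (internal cavity / blood pool), 3 = TZ (trabecular zone).
# All operations in the package consume and produce these matrices.

#' Segmentation class codes
#'
#' Named integer vector fixing the canonical label coding used throughout the
#' package: `BG = 0` (background), `EL = 1` (compacted external layer),
#' `IC = 2` (internal cavity, i.e. the blood pool), `TZ = 3` (trabecular
#' zone, the non-compacted sponge-like inner myocardium).
#'
#' @export
seg_classes <- c(BG = 0L, EL = 1L, IC = 2L, TZ = 3L)

class_name <- function(code) names(seg_classes)[match(code, seg_classes)]

#' Validate a segmentation label matrix
#'
#' Checks that `labels` is a non-empty rectangular integer matrix whose
#' values all lie in `{0, 1, 2, 3}` (see [seg_classes]) and returns it with
#' integer storage. The first offending value, if any, is reported with its
#' row/column position.
#'
#' @param labels A matrix of class labels.
#' @return The validated matrix, with integer storage mode.
#' @examples
#' validate_mask(matrix(c(0L, 1L, 2L, 3L), 2, 2))
#' @export
validate_mask <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (nrow(labels) < 1L || ncol(labels) < 1L) {
    stop("mask must have at least one row and one column")
  }
  if (!is.numeric(labels)) stop("labels must be numeric")
  bad <- which(is.na(labels) | labels != round(labels) |
                 labels < 0 | labels > 3)
  if (length(bad) > 0L) {
    pos <- arrayInd(bad[1L], dim(labels))
    stop(sprintf("invalid label value %s at (%d, %d); labels must be in 0..3",
                 format(labels[bad[1L]]), pos[1L], pos[2L]))
  }
  storage.mode(labels) <- "integer"
  labels
}

#' Voxel geometry of a short-axis slice stack
#'
#' In-plane pixel spacing plus slice thickness and inter-slice gap, all in
#' millimetres. The effective slice pitch used for volume integration is
#' `slice_thickness + slice_gap`, so gap tissue is attributed to the
#' adjacent slice. Defaults follow a typical 1.5 T short-axis cine protocol
#' (1.5 x 1.5 mm pixels, 8 mm slices, 2 mm gap).
#'
#' @param pixel_spacing_row,pixel_spacing_col In-plane spacing (mm).
#' @param slice_thickness Slice thickness (mm).
#' @param slice_gap Gap between consecutive slices (mm).
#' @return A `voxel_geometry` object.
#' @export
voxel_geometry <- function(pixel_spacing_row = 1.5, pixel_spacing_col = 1.5,
                           slice_thickness = 8, slice_gap = 2) {
  vals <- c(pixel_spacing_row, pixel_spacing_col, slice_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("pixel spacings and slice thickness must be strictly positive")
  }
  if (!is.finite(slice_gap) || slice_gap < 0) {
    stop("slice gap must be non-negative")
  }
  structure(
    list(pixel_spacing_row = pixel_spacing_row,
         pixel_spacing_col = pixel_spacing_col,
         slice_thickness = slice_thickness,
         slice_gap = slice_gap),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %.3g x %.3g mm pixels, %.3g mm slices + %.3g mm gap (pitch %.3g mm)\n",
              x$pixel_spacing_row, x$pixel_spacing_col,
              x$slice_thickness, x$slice_gap, slice_pitch(x)))
  invisible(x)
}

#' Effective slice pitch (mm)
#'
#' @param geometry A [voxel_geometry()] object.
#' @return `slice_thickness + slice_gap`.
#' @export
slice_pitch <- function(geometry) {
  geometry$slice_thickness + geometry$slice_gap
}

#' Bundle ordered slices of one patient into a stack
#'
#' @param slices List of label matrices (see [validate_mask()]), ordered
#'   along the long axis. All slices must share the same shape.
#' @param geometry Optional [voxel_geometry()]; when absent, volume
#'   computations fall back to pixel counts.
#' @param patient_id Opaque patient identifier.
#' @return A `mask_stack` object.
#' @export
mask_stack <- function(slices, geometry = NULL, patient_id = "") {
  if (!is.list(slices) || length(slices) < 1L) {
    stop("slices must be a non-empty list of label matrices")
  }
  slices <- lapply(slices, validate_mask)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices in a stack must share the same height and width")
  }
  if (!is.null(geometry) && !inherits(geometry, "voxel_geometry")) {
    stop("geometry must be a voxel_geometry object or NULL")
  }
  structure(
    list(slices = slices, geometry = geometry,
         patient_id = as.character(patient_id)),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("mask stack: %d slice(s) of %d x %d, patient '%s', geometry %s\n",
              length(x$slices), d[1], d[2], x$patient_id,
              if (is.null(x$geometry)) "absent (pixel units)" else "present"))
  invisible(x)
}

#' Default rendering palette
#'
#' Colors used when masks and difference maps are rendered to PNG. The class
#' palette follows a muted, colorblind-friendly scheme (external layer olive,
#' internal cavity cyan, trabecular zone rose); the difference palette marks
#' pixels by the *reference* class that would be restored there (green for
#' EL, blue for IC, wine red for TZ, purple for BG). `no_diff` is the neutral
#' color used for agreeing pixels in difference renderings.
#'
#' @param class_rgb,diff_rgb Named character vectors of hex colors for
#'   classes `BG`, `EL`, `IC`, `TZ`.
#' @param no_diff Hex color for the no-difference sentinel in diff renderings.
#' @return A `seg_palette` object; all nine colors must be pairwise distinct.
#' @export
default_palette <- function(class_rgb = c(BG = "#000000", EL = "#808000",
                                          IC = "#00B7C7", TZ = "#E6A3B3"),
                            diff_rgb = c(BG = "#911EB4", EL = "#3CB44B",
                                         IC = "#4363D8", TZ = "#800000"),
                            no_diff = "#D3D3D3") {
  need <- c("BG", "EL", "IC", "TZ")
  if (!all(need %in% names(class_rgb)) || !all(need %in% names(diff_rgb))) {
    stop("class_rgb and diff_rgb must name all four classes BG, EL, IC, TZ")
  }
  class_rgb <- class_rgb[need]
  diff_rgb <- diff_rgb[need]
  all_cols <- toupper(c(class_rgb, diff_rgb, no_diff))
  if (anyDuplicated(all_cols)) {
    stop("palette colors must be pairwise distinct")
  }
  structure(list(class_rgb = class_rgb, diff_rgb = diff_rgb,
                 no_diff = no_diff),
            class = "seg_palette")
}

# hex color -> integer 0..255 RGB triple
hex_to_rgb <- function(hex) {
  m <- grDevices::col2rgb(hex)
  storage.mode(m) <- "integer"
  m
}

#' Upscale a label map with nearest-neighbor sampling
#'
#' Enlarges a mask to `target_h` x `target_w` by sampling the nearest source
#' pixel (pixel-center convention). Nearest-neighbor sampling is the only
#' admissible scheme for label maps: interpolation would create fractional,
#' meaningless labels. Because the target is at least as large as the source,
#' every source pixel is sampled at least once, so the set of classes present
#' is exactly preserved.
#'
#' @param mask A label matrix.
#' @param target_h,target_w Target shape; must be >= the mask's shape.
#' @return The upscaled label matrix.
#' @export
upscale_nearest <- function(mask, target_h, target_w) {
  mask <- validate_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (target_h < h || target_w < w) {
    stop(sprintf("upscale target %d x %d is smaller than the mask (%d x %d); downscaling labels is not supported",
                 target_h, target_w, h, w))
  }
  ri <- floor((seq_len(target_h) - 0.5) * h / target_h) + 1L
  ci <- floor((seq_len(target_w) - 0.5) * w / target_w) + 1L
  mask[ri, ci, drop = FALSE]
}

#' Crop a square window focused on the left ventricle
#'
#' Extracts a `size` x `size` window. Under the default
#' `"foreground_centroid"` policy the window is centered on the centroid of
#' all non-background pixels (the ventricle), clamped so that it stays
#' within the image; an all-background mask falls back to the image center
#' with a warning. The returned offset (1-based top-left corner) makes the
#' crop invertible via [paste_back()].
#'
#' @param mask A label matrix.
#' @param size Window side length; must not exceed either image dimension.
#' @param center_policy `"foreground_centroid"` (default) or `"fixed_center"`.
#' @return A list with `mask` (the cropped window) and `offset` (`c(row, col)`
#'   of the window's top-left pixel in the source image, 1-based).
#' @export
crop_centered <- function(mask, size,
                          center_policy = c("foreground_centroid",
                                            "fixed_center")) {
  mask <- validate_mask(mask)
  center_policy <- match.arg(center_policy)
  h <- nrow(mask); w <- ncol(mask)
  if (size < 1L || size > min(h, w)) {
    stop(sprintf("crop size %d does not fit in a %d x %d image", size, h, w))
  }
  if (center_policy == "foreground_centroid") {
    fg <- which(mask != 0L)
    if (length(fg) == 0L) {
      warning("mask has no foreground pixels; falling back to fixed_center")
      center <- c((h + 1) / 2, (w + 1) / 2)
    } else {
      idx <- arrayInd(fg, dim(mask))
      center <- c(mean(idx[, 1]), mean(idx[, 2]))
    }
  } else {
    center <- c((h + 1) / 2, (w + 1) / 2)
  }
  r0 <- round(center[1] - size / 2 + 0.5)
  c0 <- round(center[2] - size / 2 + 0.5)
  r0 <- min(max(1L, r0), h - size + 1L)
  c0 <- min(max(1L, c0), w - size + 1L)
  list(mask = mask[r0:(r0 + size - 1L), c0:(c0 + size - 1L), drop = FALSE],
       offset = c(row = as.integer(r0), col = as.integer(c0)))
}

#' Paste a cropped window back into a full-size canvas
#'
#' Inverse of [crop_centered()]: places `crop` at `offset` inside an
#' all-background canvas of the stated size (or inside `canvas` if given).
#'
#' @param crop Cropped label matrix.
#' @param offset `c(row, col)` top-left position, 1-based, as returned by
#'   [crop_centered()].
#' @param height,width Canvas shape (ignored when `canvas` is supplied).
#' @param canvas Optional existing label matrix to paste into.
#' @return The full-size label matrix.
#' @export
paste_back <- function(crop, offset, height, width, canvas = NULL) {
  crop <- validate_mask(crop)
  if (is.null(canvas)) {
    canvas <- matrix(0L, height, width)
  } else {
    canvas <- validate_mask(canvas)
  }
  r0 <- offset[[1]]; c0 <- offset[[2]]
  r1 <- r0 + nrow(crop) - 1L; c1 <- c0 + ncol(crop) - 1L
  if (r0 < 1L || c0 < 1L || r1 > nrow(canvas) || c1 > ncol(canvas)) {
    stop("crop does not fit in the canvas at the given offset")
  }
  canvas[r0:r1, c0:c1] <- crop
  canvas
}

# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
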