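# Trabeculated-volume quantification. The screening statistic is the
# percentage of trabeculated myocardial volume,
#   VT% = TZ / (TZ + EL) * 100,
# where TZ is the volume of the trabecular zone and EL the volume of the
# compacted external layer; VT% above 27.4% is the conventional
# hypertrabeculation criterion for LVNC.

#' Per-class volumes of a slice stack
#'
#' Sums pixel counts per class over all slices and, when the stack carries a
#' [voxel_geometry()], converts to mm^3 using
#' `pixel_spacing_row * pixel_spacing_col * (slice_thickness + slice_gap)`
#' per pixel — the inter-slice gap is attributed to the adjacent slice, the
#' standard pitch-based convention. Without geometry, volumes are raw pixel
#' counts.
#'
#' @param stack A [mask_stack()].
#' @return A `volume_summary`: list with `el_volume`, `ic_volume`,
#'   `tz_volume` and `units` (`"mm3"` or `"pixels"`).
#' @export
class_volumes <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  counts <- Reduce(`+`, lapply(stack$slices, function(s) {
    tabulate(s + 1L, nbins = 4L)
  }))
  names(counts) <- names(seg_classes)
  if (is.null(stack$geometry)) {
    vox <- 1
    units <- "pixels"
  } else {
    g <- stack$geometry
    vox <- g$pixel_spacing_row * g$pixel_spacing_col * slice_pitch(g)
    units <- "mm3"
  }
  structure(
    list(el_volume = counts[["EL"]] * vox,
         ic_volume = counts[["IC"]] * vox,
         tz_volume = counts[["TZ"]] * vox,
         units = units),
    class = "volume_summary"
  )
}

#' @export
print.volume_summary <- function(x, ...) {
  cat(sprintf("volumes (%s): EL = %.6g, IC = %.6g, TZ = %.6g\n",
              x$units, x$el_volume, x$ic_volume, x$tz_volume))
  invisible(x)
}

#' Percentage of trabeculated myocardial volume
#'
#' `VT% = 100 * tz / (tz + el)`. The ratio is scale-invariant, so pixel
#' counts and mm^3 give the same percentage. When both volumes are zero the
#' statistic is undefined and `NA` is returned (no error).
#'
#' @param tz Trabecular-zone volume (>= 0).
#' @param el Compacted external-layer volume (>= 0).
#' @return Percentage in `[0, 100]`, or `NA` when `tz + el == 0`.
#' @export
vt_percent <- function(tz, el) {
  if (tz < 0 || el < 0) stop("volumes must be non-negative")
  if (tz + el == 0) return(NA_real_)
  100 * tz / (tz + el)
}

#' Apply the hypertrabeculation threshold criterion
#'
#' `TRUE` iff the trabeculated volume percentage lies strictly above the
#' threshold ("values above this" indicate hypertrabeculation consistent
#' with LVNC); at exactly the threshold the criterion is not met.
#'
#' @param vt VT percentage in `[0, 100]`.
#' @param threshold Diagnostic threshold percentage; default 27.4.
#' @return Logical.
#' @export
classify_lvnc <- function(vt, threshold = 27.4) {
  if (is.na(vt)) stop("vt is undefined (NA)")
  if (vt < 0 || vt > 100) stop("vt must be a percentage in [0, 100]")
  if (threshold <= 0 || threshold >= 100) {
    stop("threshold must be strictly between 0 and 100")
  }
  vt > threshold
}

#' Trabeculation percentage of a single slice
#'
#' VT% computed from the TZ and EL pixel counts of one label matrix — the
#' per-image figure displayed above each candidate during segmentation
#' review.
#'
#' @param mask A label matrix.
#' @return Percentage in `[0, 100]`, or `NA` when the slice contains neither
#'   TZ nor EL pixels.
#' @export
image_trabeculation <- function(mask) {
  mask <- validate_mask(mask)
  vt_percent(sum(mask == seg_classes[["TZ"]]),
             sum(mask == seg_classes[["EL"]]))
}
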