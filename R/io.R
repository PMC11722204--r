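# Readers and writers for mask formats (RGB PNG via the configured palette,
# NIfTI slice stacks), plus the blind-comparison bookkeeping used when
# raters pick the best of several candidate segmentations.

rgb_key <- function(r, g, b) (r * 256L + g) * 256L + b

palette_keys <- function(hex) {
  m <- hex_to_rgb(hex)
  rgb_key(m[1, ], m[2, ], m[3, ])
}

#' Read a mask from a palette-colored PNG
#'
#' Inverts the palette's class colors back to label codes. Every pixel must
#' match one of the four class colors exactly (8-bit per channel); an
#' unknown color raises an error naming the color and its location, so
#' edited or resampled images cannot be silently misread.
#'
#' @param path PNG file path.
#' @param palette A [default_palette()] object.
#' @return A label matrix.
#' @export
read_mask_png <- function(path, palette = default_palette()) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  r <- round(img[, , 1] * 255)
  g <- round(img[, , 2] * 255)
  b <- round(img[, , 3] * 255)
  keys <- rgb_key(r, g, b)
  cls <- match(keys, palette_keys(palette$class_rgb)) - 1L
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1]
    pos <- arrayInd(bad, dim(keys))
    stop(sprintf("unknown color #%02X%02X%02X at (%d, %d): not in the class palette",
                 r[bad], g[bad], b[bad], pos[1], pos[2]))
  }
  matrix(as.integer(cls), nrow(keys), ncol(keys))
}

#' Write a mask (or difference map) as a colored PNG
#'
#' In `"class"` mode each label is rendered with its class color; the file
#' round-trips losslessly through [read_mask_png()]. In `"diff"` mode the
#' input is a difference map from [compute_diff()]: difference pixels are
#' rendered in the difference palette of their reference class and agreeing
#' (`NA`) pixels in the neutral `no_diff` color.
#'
#' @param mask A label matrix (`"class"` mode) or difference map (`"diff"`).
#' @param path Output PNG path.
#' @param mode `"class"` (default) or `"diff"`.
#' @param palette A [default_palette()] object.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path, mode = c("class", "diff"),
                           palette = default_palette()) {
  mode <- match.arg(mode)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (mode == "class") {
    mask <- validate_mask(mask)
    cols <- hex_to_rgb(palette$class_rgb)
    ch_idx <- mask + 1L
  } else {
    cols <- cbind(hex_to_rgb(palette$diff_rgb), hex_to_rgb(palette$no_diff))
    ch_idx <- ifelse(is.na(mask), 5L, mask + 1L)
  }
  arr <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(cols[ch, ch_idx], nrow(mask), ncol(mask)) / 255
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a slice stack from a NIfTI volume
#'
#' The volume must be integer-valued with labels in 0..3; slices are taken
#' along the third axis. Geometry defaults to the header's pixel dimensions,
#' with the third pixdim interpreted as the slice pitch (recorded as slice
#' thickness with zero gap, which is equivalent for volume integration);
#' pass `geometry` to override, e.g. to restore an explicit thickness/gap
#' split.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param geometry Optional [voxel_geometry()] overriding the header.
#' @param patient_id Patient identifier to attach to the stack.
#' @return A [mask_stack()].
#' @export
read_stack_nifti <- function(path, geometry = NULL, patient_id = "") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("expected a 2D or 3D label volume")
  if (anyNA(arr) || any(arr != round(arr))) {
    stop("volume is not integer-valued; label stacks must contain class codes only")
  }
  if (is.null(geometry)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) >= 3 && all(pd[1:3] > 0)) {
      geometry <- voxel_geometry(pixel_spacing_row = pd[1],
                                 pixel_spacing_col = pd[2],
                                 slice_thickness = pd[3], slice_gap = 0)
    }
  }
  slices <- lapply(seq_len(dim(arr)[3]), function(k) {
    validate_mask(matrix(as.integer(arr[, , k]), dim(arr)[1], dim(arr)[2]))
  })
  mask_stack(slices, geometry = geometry, patient_id = patient_id)
}

#' Write a slice stack as a NIfTI volume
#'
#' Labels are stored as 32-bit integers; the header's pixel dimensions carry
#' the in-plane spacing and the slice pitch (`thickness + gap`), so a
#' round trip through [read_stack_nifti()] reproduces the labels bit-exactly
#' and preserves the volume-integration geometry.
#'
#' @param stack A [mask_stack()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "mask_stack"))
  d <- dim(stack$slices[[1]])
  arr <- array(0L, dim = c(d[1], d[2], length(stack$slices)))
  for (k in seq_along(stack$slices)) arr[, , k] <- stack$slices[[k]]
  img <- RNifti::asNifti(arr)
  if (!is.null(stack$geometry)) {
    g <- stack$geometry
    RNifti::pixdim(img) <- c(g$pixel_spacing_row, g$pixel_spacing_col,
                             slice_pitch(g))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Blind shuffle of candidate segmentations
#'
#' Randomly permutes the candidates so a rater cannot tell which method
#' produced which image, returning the presented (unlabeled) list and a
#' hidden key mapping each presented position back to its method. The key is
#' deliberately kept out of the presented payload.
#'
#' @param candidates Named list of at least two masks, names = method names.
#' @param seed Integer seed; the permutation is deterministic given the seed.
#' @return List with `presented` (unnamed list of masks in presentation
#'   order) and `key` (character vector: `key[i]` is the method shown at
#'   position `i`).
#' @export
blind_shuffle <- function(candidates, seed) {
  if (!is.list(candidates) || length(candidates) < 2L) {
    stop("need at least two candidates for a blind comparison")
  }
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    stop("candidates must be named by method")
  }
  perm <- with_seed(seed, sample(length(candidates)))
  list(presented = unname(candidates[perm]),
       key = names(candidates)[perm])
}

#' Build one rater-selection record
#'
#' Captures one blind-comparison decision: which presented position the
#' rater chose, the subjective quality score on the nine half-step scale
#' from 1.0 ("large diagnostically significant differences") to 5.0 ("exact
#' match"), an optional bad-quality flag for unusable source images (which
#' may carry no chosen position), and free-text feedback.
#'
#' @param image_id Image identifier.
#' @param score Quality score in `{1.0, 1.5, ..., 5.0}`; may be `NA` when
#'   `bad_quality` is set.
#' @param chosen_position 1-based presented position chosen, or `NA` when
#'   `bad_quality` is set.
#' @param n_candidates Number of presented candidates (bounds
#'   `chosen_position`).
#' @param presented_order_seed Seed used by [blind_shuffle()] for this batch.
#' @param bad_quality Flag marking the underlying image as unusable.
#' @param feedback Free text.
#' @return A `selector_record` object.
#' @export
selector_record <- function(image_id, score, chosen_position = NA_integer_,
                            n_candidates = 3L, presented_order_seed = NA_integer_,
                            bad_quality = FALSE, feedback = "") {
  allowed <- seq(1, 5, by = 0.5)
  if (!is.na(score) && !any(abs(score - allowed) < 1e-9)) {
    stop(sprintf("score %s is not one of the half-step values 1.0..5.0",
                 format(score)))
  }
  if (is.na(chosen_position)) {
    if (!bad_quality && is.na(score)) {
      stop("a record without a chosen position must be flagged bad_quality")
    }
  } else if (chosen_position < 1L || chosen_position > n_candidates) {
    stop(sprintf("chosen_position %d does not index a presented candidate (1..%d)",
                 chosen_position, n_candidates))
  }
  structure(
    list(schema_version = 1L, image_id = as.character(image_id),
         score = as.numeric(score),
         chosen_position = as.integer(chosen_position),
         n_candidates = as.integer(n_candidates),
         presented_order_seed = as.integer(presented_order_seed),
         bad_quality = isTRUE(bad_quality),
         feedback = as.character(feedback)),
    class = "selector_record"
  )
}

#' Append a selection record to a JSONL store
#'
#' The store is append-only (one JSON object per line), so independent
#' raters can write concurrently and stores can be merged by concatenation.
#'
#' @param record A [selector_record()].
#' @param path JSONL file path; created if absent.
#' @return `path`, invisibly.
#' @export
record_selection <- function(record, path) {
  stopifnot(inherits(record, "selector_record"))
  line <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, na = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Read back a JSONL selection store
#'
#' @param path JSONL file written by [record_selection()].
#' @return List of `selector_record` objects.
#' @export
read_selector_records <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    x <- jsonlite::fromJSON(l)
    structure(list(
      schema_version = as.integer(x$schema_version),
      image_id = as.character(x$image_id),
      score = if (is.null(x$score)) NA_real_ else as.numeric(x$score),
      chosen_position = if (is.null(x$chosen_position)) NA_integer_
                        else as.integer(x$chosen_position),
      n_candidates = as.integer(x$n_candidates),
      presented_order_seed = if (is.null(x$presented_order_seed)) NA_integer_
                             else as.integer(x$presented_order_seed),
      bad_quality = isTRUE(x$bad_quality),
      feedback = as.character(x$feedback)
    ), class = "selector_record")
  })
}
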