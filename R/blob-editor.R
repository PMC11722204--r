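# Headless difference-editing engine. The difference between a reference
# segmentation and an output segmentation is decomposed into connected
# "blobs", each labeled by the reference class that clicking it would
# restore; sessions track blob applications and free-hand paints and can be
# refreshed back to the unedited state.

# Connected components of a logical matrix; returns a list of m x 2
# row/col index matrices, ordered by each component's first pixel in
# column-major scan order. Adjacency built vectorized, components via igraph.
label_components <- function(on, connectivity = 4L) {
  h <- nrow(on); w <- ncol(on)
  idx <- which(on)
  if (length(idx) == 0L) return(list())
  lut <- integer(h * w)
  lut[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% h) + 1L
  edges <- integer(0)
  add_pairs <- function(shift, ok) {
    a <- idx[ok]
    b <- a + shift
    keep <- lut[b] > 0L
    c(rbind(lut[a[keep]], lut[b[keep]]))
  }
  edges <- c(edges, add_pairs(1L, rows < h))                 # down
  edges <- c(edges, add_pairs(h, idx + h <= h * w))          # right
  if (connectivity == 8L) {
    edges <- c(edges, add_pairs(h + 1L, rows < h & idx + h <= h * w))
    edges <- c(edges, add_pairs(h - 1L, rows > 1L & idx + h <= h * w))
  } else if (connectivity != 4L) {
    stop("connectivity must be 4 or 8")
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  comps <- split(idx, memb)
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  lapply(comps, function(lin) arrayInd(sort(lin), c(h, w)))
}

#' Difference map between a reference and an output segmentation
#'
#' Where the two masks disagree, the difference map carries the *reference*
#' class (the class that correcting the pixel would restore); where they
#' agree it carries the sentinel `NA`.
#'
#' @param reference,output Label matrices of the same shape.
#' @return An integer matrix with `NA` at agreeing pixels and the reference
#'   class elsewhere.
#' @export
compute_diff <- function(reference, output) {
  reference <- validate_mask(reference)
  output <- validate_mask(output)
  if (!identical(dim(reference), dim(output))) {
    stop("reference and output masks must share one shape")
  }
  d <- reference
  d[reference == output] <- NA_integer_
  d
}

#' Extract connected difference blobs
#'
#' Decomposes a difference map into connected components computed per
#' reference class: two adjacent difference pixels with different reference
#' classes belong to different blobs, mirroring the per-color rendering of
#' differences. Blobs are disjoint, cover the difference set exactly, and
#' receive deterministic ids in column-major scan order of their first
#' pixel.
#'
#' @param diff A difference map from [compute_diff()].
#' @param connectivity Pixel adjacency, `4` (default) or `8`. The default
#'   yields more, smaller, more precisely selectable blobs.
#' @return A list of `diff_blob` objects (fields `blob_id`, `ref_class`,
#'   `pixels` as an m x 2 row/col matrix, `size`, `bbox`), carrying the
#'   image shape in attribute `dim`.
#' @export
extract_blobs <- function(diff, connectivity = 4L) {
  if (!is.matrix(diff)) stop("diff must be a matrix")
  blobs <- list()
  for (cls in seg_classes) {
    on <- !is.na(diff) & diff == cls
    for (pix in label_components(on, connectivity)) {
      blobs[[length(blobs) + 1L]] <- list(
        ref_class = cls,
        pixels = pix,
        size = nrow(pix),
        bbox = c(rmin = min(pix[, 1]), rmax = max(pix[, 1]),
                 cmin = min(pix[, 2]), cmax = max(pix[, 2]))
      )
    }
  }
  if (length(blobs) > 0L) {
    first <- vapply(blobs, function(b) {
      min(b$pixels[, 1] + (b$pixels[, 2] - 1) * nrow(diff))
    }, numeric(1))
    blobs <- blobs[order(first)]
    for (i in seq_along(blobs)) {
      blobs[[i]]$blob_id <- i
      class(blobs[[i]]) <- "diff_blob"
    }
  }
  structure(blobs, dim_image = dim(diff), class = "diff_blob_list")
}

#' @export
print.diff_blob_list <- function(x, ...) {
  cat(sprintf("%d difference blob(s) on a %d x %d image\n",
              length(x), attr(x, "dim_image")[1], attr(x, "dim_image")[2]))
  invisible(x)
}

#' Find the blob containing a point
#'
#' @param blobs Result of [extract_blobs()].
#' @param point `c(row, col)`, 1-based, inside the image.
#' @return The `diff_blob` containing the point, or `NULL` if the point lies
#'   on a no-difference pixel.
#' @export
blob_at <- function(blobs, point) {
  d <- attr(blobs, "dim_image")
  r <- point[[1]]; c <- point[[2]]
  if (r < 1L || r > d[1] || c < 1L || c > d[2]) {
    stop(sprintf("point (%d, %d) is outside the %d x %d image",
                 r, c, d[1], d[2]))
  }
  for (b in blobs) {
    if (r >= b$bbox["rmin"] && r <= b$bbox["rmax"] &&
          c >= b$bbox["cmin"] && c <= b$bbox["cmax"] &&
          any(b$pixels[, 1] == r & b$pixels[, 2] == c)) {
      return(b)
    }
  }
  NULL
}

#' Find all blobs touching a rectangular region
#'
#' Drag selection: returns every blob having at least one pixel inside the
#' rectangle.
#'
#' @param blobs Result of [extract_blobs()].
#' @param rect `c(rmin, rmax, cmin, cmax)`, 1-based inclusive bounds.
#' @return A plain list of the selected `diff_blob`s.
#' @export
blobs_in_region <- function(blobs, rect) {
  d <- attr(blobs, "dim_image")
  rect <- as.integer(rect)
  if (length(rect) != 4L || rect[1] > rect[2] || rect[3] > rect[4] ||
        rect[1] < 1L || rect[2] > d[1] || rect[3] < 1L || rect[4] > d[2]) {
    stop("rect must be c(rmin, rmax, cmin, cmax), non-empty and inside the image")
  }
  hit <- vapply(blobs, function(b) {
    any(b$pixels[, 1] >= rect[1] & b$pixels[, 1] <= rect[2] &
          b$pixels[, 2] >= rect[3] & b$pixels[, 2] <= rect[4])
  }, logical(1))
  unclass(blobs)[hit]
}

#' Open a difference-editing session
#'
#' Computes the difference between `reference` and `base_output` and freezes
#' its blobs for the lifetime of the session: blob ids stay stable across
#' edits, and applied blobs are tombstoned rather than re-extracted. The
#' current output can always be reproduced by replaying the applied blob ids
#' and the paint log on the base output.
#'
#' @param reference The reference label matrix (differences restore toward
#'   it).
#' @param base_output The output label matrix being edited.
#' @param connectivity Blob connectivity, `4` (default) or `8`.
#' @return An `edit_session` object.
#' @export
edit_session <- function(reference, base_output, connectivity = 4L) {
  reference <- validate_mask(reference)
  base_output <- validate_mask(base_output)
  blobs <- extract_blobs(compute_diff(reference, base_output), connectivity)
  structure(
    list(reference = reference, base_output = base_output,
         current_output = base_output, blobs = blobs,
         applied_ids = integer(0), paint_log = list()),
    class = "edit_session"
  )
}

#' Apply one difference blob
#'
#' Sets every pixel of the blob to the blob's reference class in the current
#' output, which reduces the remaining difference to the reference by
#' exactly the blob's size. A blob can be applied once per session.
#'
#' @param session An [edit_session()].
#' @param blob_id Id of a not-yet-applied blob.
#' @return The updated session.
#' @export
apply_blob <- function(session, blob_id) {
  stopifnot(inherits(session, "edit_session"))
  ids <- vapply(session$blobs, function(b) b$blob_id, integer(1))
  if (!(blob_id %in% ids)) stop(sprintf("unknown blob id %s", blob_id))
  if (blob_id %in% session$applied_ids) {
    stop(sprintf("blob %d has already been applied", blob_id))
  }
  b <- session$blobs[[match(blob_id, ids)]]
  session$current_output[b$pixels] <- b$ref_class
  session$applied_ids <- c(session$applied_ids, as.integer(blob_id))
  session
}

#' Paint pixels with a class
#'
#' Free-hand correction: sets the given pixels to `cls` in the current
#' output and appends the stroke to the session's paint log. Brush
#' rasterization is the caller's concern; a stroke is just a set of pixels.
#'
#' @param session An [edit_session()].
#' @param cls Class code in 0..3.
#' @param pixels m x 2 matrix of row/col coordinates (1-based, in bounds).
#' @return The updated session.
#' @export
paint <- function(session, cls, pixels) {
  stopifnot(inherits(session, "edit_session"))
  if (!(cls %in% seg_classes)) stop(sprintf("invalid class code %s", cls))
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stop("pixels must be an m x 2 row/col matrix")
  d <- dim(session$current_output)
  if (any(pixels[, 1] < 1L | pixels[, 1] > d[1] |
            pixels[, 2] < 1L | pixels[, 2] > d[2])) {
    stop("paint coordinates out of bounds")
  }
  storage.mode(pixels) <- "integer"
  session$current_output[pixels] <- as.integer(cls)
  session$paint_log[[length(session$paint_log) + 1L]] <-
    list(cls = as.integer(cls), pixels = pixels)
  session
}

#' Reset a session to its unedited state
#'
#' Restores the base output and clears the applied-blob set and the paint
#' log; idempotent.
#'
#' @param session An [edit_session()].
#' @return The refreshed session, equal to a freshly opened one.
#' @export
refresh_session <- function(session) {
  stopifnot(inherits(session, "edit_session"))
  session$current_output <- session$base_output
  session$applied_ids <- integer(0)
  session$paint_log <- list()
  session
}

#' Replay a session's edits on its base output
#'
#' Recomputes the current output from the base output, the applied blob ids
#' and the paint log (in order). Used to verify that a session's state is
#' fully determined by its edit history.
#'
#' @param session An [edit_session()].
#' @return The replayed label matrix.
#' @export
replay_session <- function(session) {
  stopifnot(inherits(session, "edit_session"))
  out <- session$base_output
  ids <- vapply(session$blobs, function(b) b$blob_id, integer(1))
  for (id in session$applied_ids) {
    b <- session$blobs[[match(id, ids)]]
    out[b$pixels] <- b$ref_class
  }
  for (p in session$paint_log) {
    out[p$pixels] <- p$cls
  }
  out
}

#' @export
print.edit_session <- function(x, ...) {
  cat(sprintf("edit session: %d blob(s), %d applied, %d paint stroke(s), %d pixel(s) still differ\n",
              length(x$blobs), length(x$applied_ids), length(x$paint_log),
              sum(x$reference != x$current_output)))
  invisible(x)
}
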