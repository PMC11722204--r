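# Synthetic short-axis left-ventricle phantoms and simulated model-output
# ensembles. A phantom is a blood-pool disk (IC) surrounded by a
# trabeculated band (TZ specks over IC recesses) and a compacted outer ring
# (EL), on background. Perturbations emulate the error modes that
# segmentation refinement targets: boundary misplacement, dropped
# trabeculae, and hallucinated trabeculae in empty regions.

#' Specification of a synthetic left-ventricle phantom
#'
#' Radial anatomy, from the center outwards: internal cavity disk of radius
#' `r_cavity`; trabeculated band `(r_cavity, r_band]` in which a fraction
#' `trab_fill` of pixels is trabecular zone (the rest is blood-filled
#' intertrabecular recess, labeled internal cavity); compacted external
#' layer annulus `(r_band, r_outer]`; background outside.
#'
#' @param height,width Image shape in pixels.
#' @param center `c(row, col)` of the ventricle center; defaults to the
#'   image center.
#' @param r_cavity,r_band,r_outer Radii in pixels; must satisfy
#'   `0 < r_cavity < r_band < r_outer <= min(height, width) / 2`.
#' @param trab_fill Target fraction of band pixels set to trabecular zone,
#'   in `[0, 1]`.
#' @param speck_radius_range `c(min, max)` radius (pixels) of the random
#'   trabecular specks.
#' @param seed Integer seed; phantoms are bit-reproducible given the spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 256, width = 256, center = NULL,
                         r_cavity = 40, r_band = 70, r_outer = 90,
                         trab_fill = 0.3, speck_radius_range = c(2, 6),
                         seed = 1L) {
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (!(r_cavity > 0 && r_cavity < r_band && r_band < r_outer &&
          r_outer <= min(height, width) / 2)) {
    stop("radii must satisfy 0 < r_cavity < r_band < r_outer <= min(height, width) / 2")
  }
  if (trab_fill < 0 || trab_fill > 1) stop("trab_fill must be in [0, 1]")
  if (length(speck_radius_range) != 2L ||
        any(speck_radius_range <= 0) || diff(speck_radius_range) < 0) {
    stop("speck_radius_range must be an increasing pair of positive radii")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         center = as.numeric(center), r_cavity = r_cavity, r_band = r_band,
         r_outer = r_outer, trab_fill = trab_fill,
         speck_radius_range = as.numeric(speck_radius_range),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# squared distance of every pixel to a center, as an h x w matrix
dist2_grid <- function(h, w, center) {
  dr <- (seq_len(h) - center[1])^2
  dc <- (seq_len(w) - center[2])^2
  outer(dr, dc, `+`)
}

#' Generate a synthetic phantom with known per-class counts
#'
#' Trabecular specks are random disks placed inside the band until the
#' target fill is reached; the final speck is trimmed pixel-wise so the
#' achieved trabecular count equals `round(trab_fill * band_area)` exactly.
#' Generation is deterministic given the spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `mask` (the label matrix) and `truth`, the per-class
#'   pixel counts named `BG`, `EL`, `IC`, `TZ` (always consistent with the
#'   returned mask).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  d2 <- dist2_grid(h, w, spec$center)
  mask <- matrix(0L, h, w)
  mask[d2 <= spec$r_outer^2] <- seg_classes[["EL"]]
  mask[d2 <= spec$r_band^2] <- seg_classes[["IC"]]
  band <- d2 <= spec$r_band^2 & d2 > spec$r_cavity^2
  band_idx <- which(band)
  target <- round(spec$trab_fill * length(band_idx))
  if (target > 0L) {
    with_seed(spec$seed, {
      if (target == length(band_idx)) {
        mask[band_idx] <- seg_classes[["TZ"]]
      } else {
        is_tz <- rep(FALSE, length(band_idx))
        pos <- arrayInd(band_idx, dim(mask))
        lut <- integer(h * w); lut[band_idx] <- seq_along(band_idx)
        placed <- 0L; iter <- 0L
        while (placed < target && iter < 10000L) {
          iter <- iter + 1L
          ctr_i <- sample.int(length(band_idx), 1L)
          r <- stats::runif(1, spec$speck_radius_range[1],
                            spec$speck_radius_range[2])
          ctr <- pos[ctr_i, ]
          rr <- max(1L, floor(ctr[1] - r)):min(h, ceiling(ctr[1] + r))
          cc <- max(1L, floor(ctr[2] - r)):min(w, ceiling(ctr[2] + r))
          sub <- as.matrix(expand.grid(row = rr, col = cc))
          inside <- (sub[, 1] - ctr[1])^2 + (sub[, 2] - ctr[2])^2 <= r^2
          lin <- sub[inside, 1] + (sub[inside, 2] - 1L) * h
          bloc <- lut[lin]
          bloc <- bloc[bloc > 0L]
          new <- bloc[!is_tz[bloc]]
          if (length(new) == 0L) next
          if (placed + length(new) > target) {
            new <- sample(new, target - placed)
          }
          is_tz[new] <- TRUE
          placed <- placed + length(new)
        }
        if (placed < target) {
          rest <- which(!is_tz)
          new <- sample(rest, target - placed)
          is_tz[new] <- TRUE
        }
        mask[band_idx[is_tz]] <- seg_classes[["TZ"]]
      }
    })
  }
  truth <- tabulate(mask + 1L, nbins = 4L)
  names(truth) <- names(seg_classes)
  list(mask = mask, truth = truth)
}

#' Specification of segmentation-output noise
#'
#' Models the three error kinds that refinement addresses, applied in a
#' fixed order (boundary jitter, then trabecula dropout, then hallucination)
#' from one seeded random stream. The order matters because the steps do not
#' commute; it is fixed so results are reproducible.
#'
#' @param boundary_jitter Maximum displacement (pixels) of class boundaries,
#'   realized as a smooth random warp of the label map.
#' @param hallucination_rate Expected number of spurious trabecular blobs
#'   added per image (Poisson); blobs are placed only in background regions.
#' @param hallucination_radius_range `c(min, max)` radius (pixels) of
#'   hallucinated blobs.
#' @param dropout_rate Probability that each true trabecular speck
#'   (connected component) is erased and filled with its surrounding class.
#' @param seed Integer seed.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(boundary_jitter = 0, hallucination_rate = 0,
                              hallucination_radius_range = c(2, 5),
                              dropout_rate = 0, seed = 1L) {
  if (boundary_jitter < 0 || hallucination_rate < 0) {
    stop("rates and radii must be non-negative")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("dropout_rate must be in [0, 1]")
  }
  if (length(hallucination_radius_range) != 2L ||
        any(hallucination_radius_range <= 0) ||
        diff(hallucination_radius_range) < 0) {
    stop("hallucination_radius_range must be an increasing pair of positive radii")
  }
  structure(
    list(boundary_jitter = boundary_jitter,
         hallucination_rate = hallucination_rate,
         hallucination_radius_range = as.numeric(hallucination_radius_range),
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "perturbation_spec"
  )
}

# Smooth random warp: offsets drawn on a coarse control grid, bilinearly
# interpolated to full resolution, then used to resample labels
# nearest-neighbor. Max displacement is bounded by `jitter`.
warp_labels <- function(mask, jitter, grid_step = 16L) {
  h <- nrow(mask); w <- ncol(mask)
  gh <- max(2L, ceiling(h / grid_step) + 1L)
  gw <- max(2L, ceiling(w / grid_step) + 1L)
  dy <- matrix(stats::runif(gh * gw, -jitter, jitter), gh, gw)
  dx <- matrix(stats::runif(gh * gw, -jitter, jitter), gh, gw)
  interp_axis <- function(n, g) {
    # n x g matrix of bilinear weights along one axis
    t <- (seq_len(n) - 1) / max(1L, n - 1L) * (g - 1L) + 1
    i0 <- pmin(floor(t), g - 1L)
    f <- t - i0
    m <- matrix(0, n, g)
    m[cbind(seq_len(n), i0)] <- 1 - f
    m[cbind(seq_len(n), i0 + 1L)] <- f
    m
  }
  ar <- interp_axis(h, gh)
  ac <- interp_axis(w, gw)
  dy_full <- ar %*% dy %*% t(ac)
  dx_full <- ar %*% dx %*% t(ac)
  src_r <- pmin(pmax(round(row(mask) + dy_full), 1L), h)
  src_c <- pmin(pmax(round(col(mask) + dx_full), 1L), w)
  out <- mask
  out[] <- mask[cbind(as.vector(src_r), as.vector(src_c))]
  out
}

# Erase one connected component, filling it with the most common
# non-trabecular label among its 8-neighborhood; background if none.
erase_component <- function(mask, pix) {
  h <- nrow(mask); w <- ncol(mask)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  neigh <- integer(0)
  for (k in seq_len(nrow(off))) {
    nr <- pix[, 1] + off$dr[k]; nc <- pix[, 2] + off$dc[k]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    neigh <- c(neigh, mask[cbind(nr[ok], nc[ok])])
  }
  neigh <- neigh[neigh != seg_classes[["TZ"]]]
  fill <- if (length(neigh) == 0L) seg_classes[["BG"]] else {
    as.integer(names(which.max(table(neigh))))
  }
  mask[pix] <- fill
  mask
}

#' Apply simulated segmentation noise to a mask
#'
#' Applies, in order: smooth boundary jitter, trabecular-speck dropout, and
#' trabecular hallucinations in background regions. With all rates zero the
#' input is returned unchanged. Deterministic given the spec's seed; the
#' caller's RNG state is untouched.
#'
#' @param mask A label matrix.
#' @param pspec A [perturbation_spec()].
#' @return A perturbed label matrix of the same shape.
#' @export
perturb <- function(mask, pspec) {
  mask <- validate_mask(mask)
  stopifnot(inherits(pspec, "perturbation_spec"))
  if (pspec$boundary_jitter == 0 && pspec$dropout_rate == 0 &&
        pspec$hallucination_rate == 0) {
    return(mask)
  }
  with_seed(pspec$seed, {
    if (pspec$boundary_jitter > 0) {
      mask <- warp_labels(mask, pspec$boundary_jitter)
    }
    if (pspec$dropout_rate > 0) {
      comps <- label_components(mask == seg_classes[["TZ"]], connectivity = 4L)
      for (pix in comps) {
        if (stats::runif(1) < pspec$dropout_rate) {
          mask <- erase_component(mask, pix)
        }
      }
    }
    if (pspec$hallucination_rate > 0) {
      k <- stats::rpois(1, pspec$hallucination_rate)
      bg <- which(mask == seg_classes[["BG"]])
      h <- nrow(mask); w <- ncol(mask)
      for (i in seq_len(k)) {
        if (length(bg) == 0L) break
        ctr <- arrayInd(bg[sample.int(length(bg), 1L)], dim(mask))
        r <- stats::runif(1, pspec$hallucination_radius_range[1],
                          pspec$hallucination_radius_range[2])
        rr <- max(1L, floor(ctr[1] - r)):min(h, ceiling(ctr[1] + r))
        cc <- max(1L, floor(ctr[2] - r)):min(w, ceiling(ctr[2] + r))
        sub <- as.matrix(expand.grid(row = rr, col = cc))
        inside <- (sub[, 1] - ctr[1])^2 + (sub[, 2] - ctr[2])^2 <= r^2
        sub <- sub[inside, , drop = FALSE]
        keep <- mask[sub] == seg_classes[["BG"]]
        mask[sub[keep, , drop = FALSE]] <- seg_classes[["TZ"]]
      }
    }
    mask
  })
}

#' Simulate an ensemble of model-output masks
#'
#' Produces `n` independent perturbations of `mask`, standing in for the
#' outputs of independently trained segmentation models. The `agreement`
#' level scales all perturbation rates by `1 - agreement`: at `agreement = 1`
#' all members equal `mask` exactly; lower agreement injects stronger
#' per-member independent noise. Member `i` uses seed `pspec$seed + i`, so
#' the ensemble is deterministic given the spec.
#'
#' @param mask The underlying (true) label matrix.
#' @param n Number of ensemble members (>= 1).
#' @param pspec A [perturbation_spec()] giving the full-strength noise model.
#' @param agreement Ensemble agreement level in `[0, 1]`.
#' @return A list of `n` label matrices.
#' @export
simulate_ensemble <- function(mask, n, pspec, agreement = 1) {
  mask <- validate_mask(mask)
  if (n < 1L) stop("ensemble size n must be at least 1")
  if (agreement < 0 || agreement > 1) stop("agreement must be in [0, 1]")
  scale <- 1 - agreement
  lapply(seq_len(n), function(i) {
    if (scale == 0) return(mask)
    pi <- perturbation_spec(
      boundary_jitter = pspec$boundary_jitter * scale,
      hallucination_rate = pspec$hallucination_rate * scale,
      hallucination_radius_range = pspec$hallucination_radius_range,
      dropout_rate = pspec$dropout_rate * scale,
      seed = pspec$seed + i
    )
    perturb(mask, pi)
  })
}
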