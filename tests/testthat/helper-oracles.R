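# Independent oracles for the core operations, deliberately written with
# different algorithms than the implementation (per-pixel loops, explicit
# flood fill, set arithmetic).

random_mask <- function(h, w) {
  matrix(sample(0:3, h * w, replace = TRUE), h, w)
}

# per-pixel vote counting, looped
consensus_oracle <- function(original, preds, m) {
  out <- original
  for (j in seq_len(ncol(original))) {
    for (i in seq_len(nrow(original))) {
      votes <- tabulate(vapply(preds, function(p) p[i, j], integer(1)) + 1L,
                        nbins = 4L)
      if (max(votes) >= m) out[i, j] <- which.max(votes) - 1L
    }
  }
  out
}

# explicit stack-based flood fill over per-class difference pixels,
# discovered in column-major scan order
flood_components_oracle <- function(diff, connectivity = 4L) {
  h <- nrow(diff); w <- ncol(diff)
  seen <- matrix(FALSE, h, w)
  nbr <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  }
  comps <- list()
  for (c0 in seq_len(w)) {
    for (r0 in seq_len(h)) {
      if (is.na(diff[r0, c0]) || seen[r0, c0]) next
      cls <- diff[r0, c0]
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      members <- integer(0)
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        members <- c(members, p[1] + (p[2] - 1L) * h)
        for (k in seq_len(nrow(nbr))) {
          nr <- p[1] + nbr[k, 1]; nc <- p[2] + nbr[k, 2]
          if (nr >= 1L && nr <= h && nc >= 1L && nc <= w &&
                !seen[nr, nc] && !is.na(diff[nr, nc]) &&
                diff[nr, nc] == cls) {
            seen[nr, nc] <- TRUE
            stack[[length(stack) + 1L]] <- c(nr, nc)
          }
        }
      }
      comps[[length(comps) + 1L]] <- list(cls = cls, members = sort(members))
    }
  }
  comps
}

# blobs -> same shape as the flood oracle output for direct comparison
blobs_as_sets <- function(blobs) {
  h <- attr(blobs, "dim_image")[1]
  lapply(unclass(blobs), function(b) {
    list(cls = b$ref_class,
         members = sort(b$pixels[, 1] + (b$pixels[, 2] - 1L) * h))
  })
}

# set-based Dice
dice_oracle <- function(a, b, cls) {
  A <- which(a == cls); B <- which(b == cls)
  if (length(A) + length(B) == 0L) return(NA_real_)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

hamming <- function(a, b) sum(a != b)
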