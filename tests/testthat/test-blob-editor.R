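test_that("difference maps mark disagreements with the reference class", {
  a <- random_mask(8, 8)
  expect_true(all(is.na(compute_diff(a, a))))

  ref <- matrix(1L, 4, 4); out <- matrix(0L, 4, 4)
  d <- compute_diff(ref, out)
  expect_true(all(d == 1L))

  set.seed(3)
  for (i in 1:10) {
    r <- random_mask(10, 10); o <- random_mask(10, 10)
    d <- compute_diff(r, o)
    expect_identical(sum(!is.na(d)), hamming(r, o))
    expect_true(all(d[!is.na(d)] == r[!is.na(d)]))
  }
  expect_error(compute_diff(random_mask(3, 3), random_mask(4, 3)), "shape")
})

test_that("connectivity semantics split or join diagonal neighbors", {
  ref <- matrix(0L, 3, 3); out <- matrix(0L, 3, 3)
  ref[1, 1] <- 1L; ref[2, 2] <- 1L   # two diagonal EL differences
  d <- compute_diff(ref, out)
  expect_length(extract_blobs(d, connectivity = 4L), 2L)
  expect_length(extract_blobs(d, connectivity = 8L), 1L)
})

test_that("adjacent differences of different reference classes stay separate", {
  ref <- matrix(0L, 2, 2); out <- matrix(0L, 2, 2)
  ref[1, 1] <- 1L; ref[2, 1] <- 3L   # vertically adjacent EL and TZ diffs
  blobs <- extract_blobs(compute_diff(ref, out), connectivity = 4L)
  expect_length(blobs, 2L)
  expect_setequal(vapply(blobs, function(b) b$ref_class, integer(1)), c(1L, 3L))
})

test_that("blob extraction matches the flood-fill oracle and partitions the diff set", {
  set.seed(7)
  for (conn in c(4L, 8L)) {
    for (i in 1:10) {
      ref <- random_mask(24, 24); out <- random_mask(24, 24)
      d <- compute_diff(ref, out)
      blobs <- extract_blobs(d, connectivity = conn)
      expect_identical(blobs_as_sets(blobs),
                       flood_components_oracle(d, connectivity = conn))
      all_pix <- unlist(lapply(blobs_as_sets(blobs), `[[`, "members"))
      expect_identical(sort(all_pix), which(!is.na(d)))  # disjoint cover
      # bbox tightness and size bookkeeping
      for (b in blobs) {
        expect_identical(b$size, nrow(b$pixels))
        expect_identical(unname(b$bbox),
                         c(min(b$pixels[, 1]), max(b$pixels[, 1]),
                           min(b$pixels[, 2]), max(b$pixels[, 2])))
      }
    }
  }
  expect_length(extract_blobs(compute_diff(matrix(0L, 3, 3), matrix(0L, 3, 3))),
                0L)
})

test_that("point lookup resolves every blob pixel and rejects bad points", {
  set.seed(13)
  ref <- random_mask(12, 12); out <- random_mask(12, 12)
  blobs <- extract_blobs(compute_diff(ref, out))
  for (b in unclass(blobs)) {
    for (k in seq_len(b$size)) {
      hit <- blob_at(blobs, b$pixels[k, ])
      expect_identical(hit$blob_id, b$blob_id)
    }
  }
  agree <- which(ref == out)
  if (length(agree) > 0) {
    expect_null(blob_at(blobs, arrayInd(agree[1], c(12L, 12L))[1, ]))
  }
  expect_error(blob_at(blobs, c(0, 5)), "outside")
  expect_error(blob_at(blobs, c(5, 13)), "outside")
})

test_that("region selection returns exactly the blobs touching the rectangle", {
  ref <- matrix(0L, 10, 10); out <- matrix(0L, 10, 10)
  ref[2, 2] <- 1L; ref[8, 8] <- 2L
  blobs <- extract_blobs(compute_diff(ref, out))
  expect_length(blobs_in_region(blobs, c(1, 10, 1, 10)), 2L)
  expect_length(blobs_in_region(blobs, c(4, 6, 4, 6)), 0L)
  sel <- blobs_in_region(blobs, c(1, 3, 1, 3))
  expect_length(sel, 1L)
  expect_identical(sel[[1]]$ref_class, 1L)

  set.seed(17)
  ref <- random_mask(15, 15); out <- random_mask(15, 15)
  blobs <- extract_blobs(compute_diff(ref, out))
  rect <- c(3, 9, 5, 12)
  sel_ids <- vapply(blobs_in_region(blobs, rect), `[[`, integer(1), "blob_id")
  brute <- vapply(unclass(blobs), function(b) {
    any(b$pixels[, 1] >= rect[1] & b$pixels[, 1] <= rect[2] &
          b$pixels[, 2] >= rect[3] & b$pixels[, 2] <= rect[4])
  }, logical(1))
  expect_setequal(sel_ids, which(brute))
  expect_error(blobs_in_region(blobs, c(5, 3, 1, 2)), "rect")
})

test_that("applying a blob restores its pixels and shrinks the difference by its size", {
  set.seed(19)
  ref <- random_mask(16, 16); out <- random_mask(16, 16)
  s <- edit_session(ref, out)
  for (b in unclass(s$blobs)) {
    before <- hamming(ref, s$current_output)
    s <- apply_blob(s, b$blob_id)
    expect_identical(hamming(ref, s$current_output), before - b$size)
  }
  expect_identical(s$current_output, ref)   # convergence
  expect_error(apply_blob(s, s$blobs[[1]]$blob_id), "already")
  expect_error(apply_blob(s, 9999L), "unknown")
})

test_that("painting, refreshing, and replaying a session behave as logged", {
  set.seed(23)
  ref <- random_mask(10, 10); out <- random_mask(10, 10)
  s <- edit_session(ref, out)
  all_pix <- as.matrix(expand.grid(row = 1:10, col = 1:10))
  s <- paint(s, 0L, all_pix)
  expect_true(all(s$current_output == 0L))

  s <- apply_blob(refresh_session(s), s$blobs[[1]]$blob_id)
  s <- paint(s, 3L, cbind(4:6, 4:6))
  s <- paint(s, 2L, cbind(1, 1))
  expect_identical(replay_session(s), s$current_output)

  r <- refresh_session(s)
  expect_identical(r$current_output, out)
  expect_length(r$applied_ids, 0L)
  expect_length(r$paint_log, 0L)
  expect_identical(refresh_session(r)[], r[])  # idempotent

  expect_error(paint(s, 7L, cbind(1, 1)), "invalid class")
  expect_error(paint(s, 1L, cbind(0, 1)), "out of bounds")
})
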