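test_that("validate_mask accepts exactly the grids with labels in 0..3", {
  expect_identical(validate_mask(matrix(c(0, 1, 2, 3), 2, 2)),
                   matrix(c(0L, 1L, 2L, 3L), 2, 2))
  expect_identical(validate_mask(matrix(0L, 3, 3)), matrix(0L, 3, 3))
  expect_error(validate_mask(matrix(4L, 1, 1)), "4.*\\(1, 1\\)")
  expect_error(validate_mask(matrix(c(0L, -1L), 1, 2)), "-1")
  expect_error(validate_mask(matrix(c(0.5, 1), 1, 2)), "invalid label")
  expect_error(validate_mask(1:4), "matrix")
  set.seed(11)
  for (i in 1:20) {
    m <- random_mask(sample(1:8, 1), sample(1:8, 1))
    expect_identical(validate_mask(m), m)
  }
})

test_that("nearest-neighbor upscaling expands blocks and preserves classes", {
  src <- matrix(c(1L, 3L, 2L, 0L), 2, 2)
  up <- upscale_nearest(src, 4, 4)
  expect_identical(up, src[rep(1:2, each = 2), rep(1:2, each = 2)])
  expect_identical(upscale_nearest(src, 2, 2), src)
  expect_error(upscale_nearest(src, 1, 4), "smaller")

  set.seed(21)
  for (i in 1:10) {
    m <- random_mask(17, 23)
    up <- upscale_nearest(m, 51, 64)
    expect_setequal(unique(as.vector(up)), unique(as.vector(m)))
  }
})

test_that("upscaling to a non-integer factor preserves class area fractions", {
  set.seed(31)
  for (i in 1:5) {
    m <- random_mask(64, 64)
    up <- upscale_nearest(m, 200, 200)
    before <- tabulate(m + 1L, 4L) / length(m)
    after <- tabulate(up + 1L, 4L) / length(up)
    expect_true(all(abs(before - after) < 0.01))
  }
})

make_lv_mask <- function(h, w, center, r) {
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, `+`)
  m <- matrix(0L, h, w)
  m[d2 <= r^2] <- 1L
  m
}

test_that("centroid crop contains the ventricle and is invertible", {
  m <- make_lv_mask(120, 120, c(60, 60), 20)
  cr <- crop_centered(m, 64)
  expect_identical(dim(cr$mask), c(64L, 64L))
  expect_identical(sum(cr$mask != 0L), sum(m != 0L))
  back <- paste_back(cr$mask, cr$offset, 120, 120)
  expect_identical(back, m)
})

test_that("crop window is clamped at image edges", {
  # ventricle near the top-left corner: the naive centered window would
  # leave the image; brute-force check the clamped window stays in bounds
  m <- make_lv_mask(100, 100, c(15, 12), 10)
  cr <- crop_centered(m, 60)
  off <- cr$offset
  expect_true(off["row"] >= 1 && off["col"] >= 1)
  expect_true(off["row"] + 60 - 1 <= 100 && off["col"] + 60 - 1 <= 100)
  expect_identical(off, c(row = 1L, col = 1L))
  expect_identical(paste_back(cr$mask, cr$offset, 100, 100), m)
})

test_that("degenerate crops error or fall back as documented", {
  m <- make_lv_mask(50, 50, c(25, 25), 8)
  expect_error(crop_centered(m, 51), "does not fit")
  expect_warning(cr <- crop_centered(matrix(0L, 50, 50), 20),
                 "fixed_center")
  expect_identical(cr$offset, c(row = 16L, col = 16L))
})

test_that("the palette requires four classes and distinct colors", {
  pal <- default_palette()
  expect_named(pal$class_rgb, c("BG", "EL", "IC", "TZ"))
  expect_error(default_palette(class_rgb = c(BG = "#000000", EL = "#808000",
                                             IC = "#00B7C7", TZ = "#808000")),
               "distinct")
  expect_error(default_palette(class_rgb = c(BG = "#000000")), "all four")
})

test_that("stacks require consistent slice shapes and valid geometry", {
  s <- random_mask(6, 6)
  expect_error(mask_stack(list(s, random_mask(5, 6))), "same height")
  expect_error(mask_stack(list()), "non-empty")
  g <- voxel_geometry(1.5, 1.5, 8, 2)
  expect_equal(slice_pitch(g), 10)
  expect_error(voxel_geometry(slice_thickness = 0), "positive")
  st <- mask_stack(list(s, s), g, "p1")
  expect_length(st$slices, 2)
})
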