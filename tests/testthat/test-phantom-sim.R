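small_spec <- function(...) {
  phantom_spec(height = 128, width = 128, r_cavity = 20, r_band = 35,
               r_outer = 45, ...)
}

test_that("phantom fill extremes behave exactly", {
  p0 <- generate_phantom(small_spec(trab_fill = 0, seed = 1))
  expect_identical(p0$truth[["TZ"]], 0L)
  expect_setequal(unique(as.vector(p0$mask)), c(0L, 1L, 2L))

  p1 <- generate_phantom(small_spec(trab_fill = 1, seed = 1))
  d2 <- outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, `+`)
  band_n <- sum(d2 <= 35^2 & d2 > 20^2)
  expect_identical(p1$truth[["TZ"]], band_n)
})

test_that("phantom hits the fill target and is seed-reproducible", {
  sp <- small_spec(trab_fill = 0.4, seed = 42)
  p <- generate_phantom(sp)
  d2 <- outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, `+`)
  band_n <- sum(d2 <= 35^2 & d2 > 20^2)
  expect_lt(abs(p$truth[["TZ"]] / band_n - 0.4), 0.05)
  expect_identical(generate_phantom(sp)$mask, p$mask)
})

test_that("truth counts always match the returned mask and anatomy is radial", {
  for (fill in c(0.15, 0.5, 0.85)) {
    p <- generate_phantom(small_spec(trab_fill = fill, seed = 7))
    counts <- tabulate(p$mask + 1L, 4L)
    expect_identical(unname(p$truth), counts)
    d2 <- outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, `+`)
    # IC and TZ confined to r_band; EL confined to (r_band, r_outer]
    expect_true(all(d2[p$mask == 2L | p$mask == 3L] <= 35^2 + 1e-9))
    expect_true(all(d2[p$mask == 1L] > 35^2 & d2[p$mask == 1L] <= 45^2 + 1e-9))
  }
})

test_that("phantom_spec rejects invalid radii and fills", {
  expect_error(phantom_spec(r_cavity = 50, r_band = 40), "radii")
  expect_error(phantom_spec(r_outer = 200), "radii")
  expect_error(phantom_spec(trab_fill = 1.2), "trab_fill")
})

test_that("perturbation with zero rates is the identity", {
  p <- generate_phantom(small_spec(seed = 3))
  expect_identical(perturb(p$mask, perturbation_spec()), p$mask)
})

test_that("perturbation is deterministic and leaves the RNG state alone", {
  p <- generate_phantom(small_spec(seed = 3))
  ps <- perturbation_spec(boundary_jitter = 2, hallucination_rate = 1,
                          dropout_rate = 0.3, seed = 9)
  set.seed(123); before <- stats::runif(1)
  set.seed(123); a <- perturb(p$mask, ps); after <- stats::runif(1)
  expect_identical(before, after)
  expect_identical(a, perturb(p$mask, ps))
})

test_that("pure hallucination adds about the expected number of components", {
  p <- generate_phantom(small_spec(trab_fill = 0.3, seed = 5))
  n_new <- vapply(1:60, function(s) {
    out <- perturb(p$mask, perturbation_spec(hallucination_rate = 3, seed = s))
    changed <- out != p$mask
    # changes are TZ pixels added on former background only
    expect_true(all(out[changed] == 3L & p$mask[changed] == 0L))
    length(blobs_as_sets(extract_blobs(compute_diff(out, p$mask))))
  }, numeric(1))
  expect_gt(mean(n_new), 2.3)
  expect_lt(mean(n_new), 3.7)
})

test_that("moderate boundary jitter keeps per-class Dice high", {
  sp <- phantom_spec(trab_fill = 0.3, seed = 13)
  p <- generate_phantom(sp)
  out <- perturb(p$mask, perturbation_spec(boundary_jitter = 2, seed = 17))
  rep <- dice_report(p$mask, out)
  expect_true(all(rep$per_class >= 0.7))
})

test_that("ensemble agreement controls member similarity", {
  p <- generate_phantom(small_spec(trab_fill = 0.3, seed = 19))
  ps <- perturbation_spec(boundary_jitter = 3, hallucination_rate = 2,
                          dropout_rate = 0.2, seed = 23)
  exact <- simulate_ensemble(p$mask, 4, ps, agreement = 1)
  expect_true(all(vapply(exact, identical, logical(1), p$mask)))

  pair_dice <- function(members) {
    pairs <- utils::combn(length(members), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      dice_report(members[[pairs[1, k]]], members[[pairs[2, k]]])$average
    }, numeric(1)))
  }
  hi <- pair_dice(simulate_ensemble(p$mask, 4, ps, agreement = 0.9))
  lo <- pair_dice(simulate_ensemble(p$mask, 4, ps, agreement = 0.5))
  expect_gt(hi, lo)
  expect_error(simulate_ensemble(p$mask, 0, ps), "at least 1")
})
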