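test_that("default composition uses four peaks pulled back 6 mm apart", {
  ranges <- vapply(canonical$peaks, function(p) p$nominal_range, 0)
  expect_equal(ranges, c(150, 144, 138, 132))
  expect_equal(length(coef(canonical)), 4L)
})

test_that("a single-peak SOBP gets weight prescription / peak max", {
  b1 <- sobp(distal_range = 150, n_peaks = 1, prescription = 80)
  expect_equal(unname(coef(b1)), 80)   # pristine curves are max-normalized
  expect_equal(max(b1$physical$values), 80, tolerance = 1e-12)
})

test_that("duplicate peaks are tie-broken to the minimum-norm equal split", {
  g <- seq(0, 180, 0.1)
  pk <- pristine_peak(150)
  pl <- c(peak_max_depth(pk) - 8, peak_max_depth(pk))
  w1 <- solve_weights(list(pk), pl, 100, g)
  expect_warning(
    w2 <- solve_weights(list(pk, pristine_peak(150)), pl, 100, g),
    "duplicate")
  expect_equal(sum(w2), sum(w1), tolerance = 1e-9)
  expect_equal(w2[1], w2[2])
})

test_that("solved weights are non-negative across a range of compositions", {
  for (n in c(2, 5, 8)) {
    for (R in c(90, 150)) {
      b <- sobp(distal_range = R, n_peaks = n, spacing = 6, grid_max = R + 30)
      expect_true(all(b$weights >= 0), label = sprintf("n=%d R=%g", n, R))
      expect_gt(sum(b$weights), 0)
    }
  }
})

test_that("the default physical plateau is flat to within 2%", {
  expect_lte(flatness(canonical$physical, canonical$plateau), 2)
})

test_that("plateau dose stays within 5% of the prescription", {
  sel <- canonical$grid >= canonical$plateau[1] & canonical$grid <= canonical$plateau[2]
  expect_lt(max(abs(canonical$physical$values[sel] - 100)), 5)
})

test_that("compose is linear in the weights", {
  g <- seq(0, 180, 0.1)
  peaks <- canonical$peaks
  w <- canonical$weights
  b <- weighted_beam(peaks, w)
  b_scaled <- weighted_beam(peaks, 3 * w)
  expect_equal(compose(b_scaled, g)$values, 3 * compose(b, g)$values)
  w2 <- rev(w)
  b2 <- weighted_beam(peaks, w2)
  bsum <- weighted_beam(peaks, w + w2)
  expect_equal(compose(bsum, g)$values,
               compose(b, g)$values + compose(b2, g)$values,
               tolerance = 1e-12)
  one <- weighted_beam(peaks, c(0, 0, 5, 0))
  expect_equal(compose(one, g)$values,
               5 * pristine_depth_dose(peaks[[3]], g)$values)
})

test_that("composed dose is negligible beyond the deepest straggled range", {
  sig_max <- max(vapply(canonical$peaks, function(p) p$sigma, 0))
  deep <- canonical$grid >= 150 + 10 * sig_max
  expect_true(any(deep))   # the default grid must reach that far
  expect_true(all(canonical$physical$values[deep] < 1e-4 * canonical$prescription))
})

test_that("degenerate configurations are rejected", {
  expect_error(sobp(n_peaks = 0), ">= 1")
  expect_error(sobp(spacing = -2), "> 0")
  expect_error(sobp(distal_range = 10, n_peaks = 4, spacing = 6), "<= 0")
  expect_error(sobp(n_peaks = 2, plateau_margin = 10), "empty")
  pk <- pristine_peak(150)
  expect_error(solve_weights(list(pk), c(149, 149.5), 100, seq(0, 180, 0.1)),
               "at least 10")
})
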