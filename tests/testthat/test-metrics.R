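test_that("flatness is zero for a constant curve and exact for a known ripple", {
  g <- seq(0, 11, 1) / 2            # 12 points, 0.5 mm spacing
  expect_equal(flatness(depth_dose(g, rep(42, 12)), c(0, 6)), 0)
  v <- rep(c(99, 100, 101), 4)
  expect_equal(flatness(depth_dose(g, v), c(0, 6)), 2.0)
  expect_equal(flatness(depth_dose(g, 7 * v), c(0, 6)), 2.0)  # scale-invariant
  expect_error(flatness(depth_dose(g, v), c(0, 2)), "at least 10")
})

test_that("range_at interpolates distal crossings", {
  g <- seq(0, 100, 0.5)
  step <- depth_dose(g, ifelse(g <= 50, 100, 0))
  expect_lt(abs(range_at(step, 0.9, 100) - 50), 0.5 + 1e-12)
  ramp <- depth_dose(g, pmin(100, pmax(0, 100 * (60 - g) / 10)))
  expect_equal(range_at(ramp, 0.5, 100), 55)
  expect_gte(range_at(ramp, 0.8, 100), range_at(ramp, 0.9, 100))
  # no crossing: all below, or still above at the end of the grid
  expect_error(range_at(depth_dose(g, rep(1, length(g))), 0.9, 100),
               class = "rangemod_range_undefined")
  expect_error(range_at(depth_dose(g, rep(100, length(g))), 0.9, 100),
               class = "rangemod_range_undefined")
})

test_that("range_at agrees with a brute-force scan on random monotone-falloff curves", {
  set.seed(42)
  g <- seq(0, 120, 0.25)
  for (i in 1:25) {
    curve <- random_falloff_curve(g)
    f <- stats::runif(1, 0.1, 0.9)
    ref <- max(curve$values)
    got <- range_at(curve, f, ref)
    scan <- max(g[curve$values >= f * ref])   # deepest grid point above threshold
    expect_lt(abs(got - scan), 0.25 + 1e-12)
  }
})

test_that("biological range extension vanishes without saturation and stays in band", {
  expect_equal(bio_range_extension(canonical, rbe_params(saturation = 0)), 0,
               tolerance = 1e-9)
  ext <- bio_range_extension(canonical)
  expect_gt(ext, 0)
  expect_lte(ext, 2)
})

test_that("range extension is non-decreasing in the saturation level", {
  exts <- vapply(c(0, 0.1, 0.2, 0.35), function(a)
    bio_range_extension(canonical, rbe_params(saturation = a)), 0)
  expect_true(all(diff(exts) >= -1e-9))
})

test_that("terminal mean RBE equals the baseline without saturation and stays in bounds", {
  expect_equal(terminal_mean_rbe(canonical, rbe_params(saturation = 0)), 1.1,
               tolerance = 1e-12)
  tmr <- terminal_mean_rbe(canonical)
  expect_gt(tmr, 1.1)
  expect_lt(tmr, 1.1 * 1.35)
  expect_error(terminal_mean_rbe(canonical, window = 0), "> 0")
})

test_that("metric comparisons flag directions and are antisymmetric", {
  m0 <- beam_metrics(canonical)
  m2 <- beam_metrics(canonical, scheme = two_way_scheme())
  self <- compare_metrics(m0, m0)
  expect_true(all(self$flag == "unchanged"))
  fwd <- compare_metrics(m0, m2)
  bwd <- compare_metrics(m2, m0)
  expect_equal(fwd$delta, -bwd$delta)
  expect_equal(fwd$flag[fwd$metric == "terminal_mean_rbe"], "improved")
  expect_equal(fwd$flag[fwd$metric == "distal_hotspot_ratio"], "improved")
})

test_that("the metrics report is internally consistent", {
  m <- beam_metrics(canonical)
  expect_s3_class(m, "metrics_report")
  expect_equal(m$range_extension, m$r90_biological - m$r90_physical)
  expect_gt(m$flatness_biological, m$flatness_physical)
  # integral dose beyond deeper depths can only shrink
  expect_true(all(diff(m$dose_beyond) < 0))
})
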