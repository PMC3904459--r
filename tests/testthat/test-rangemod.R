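test_that("two-way scheme splits the dose in half with a 3 mm pull-back", {
  s <- two_way_scheme()
  expect_equal(s$shifts, c(0, -3))
  expect_equal(s$fractions, c(0.5, 0.5))
  expect_equal(sum(s$fractions), 1)
  expect_equal(two_way_scheme(6)$shifts, c(0, -6))
  expect_equal(two_way_scheme(3, direction = "extend")$shifts, c(0, 3))
  expect_error(two_way_scheme(0), "positive")
  expect_error(two_way_scheme(-2), "positive")
})

test_that("three-way scheme steps the range by 2 mm per beam", {
  s <- three_way_scheme()
  expect_equal(s$shifts, c(0, -2, -4))
  expect_equal(s$fractions, rep(1 / 3, 3))
  expect_equal(three_way_scheme(3)$shifts, c(0, -3, -6))
  expect_error(three_way_scheme(0), "positive")
})

test_that("scheme validation enforces distinct shifts and unit fractions", {
  expect_error(modulation_scheme(c(0, 0), c(0.5, 0.5)), "distinct")
  expect_error(modulation_scheme(c(0, -3), c(0.5, 0.4)), "sum to 1")
  expect_error(modulation_scheme(c(0, -3), c(1.2, -0.2)), "> 0")
})

test_that("the identity scheme reproduces the unmodulated curves bit for bit", {
  md <- modulated_dose(canonical, modulation_scheme(0, 1))
  expect_identical(md$physical$values, canonical$physical$values)
  expect_identical(md$biological$values, canonical$biological$values)
})

test_that("total weight is conserved by any scheme", {
  for (s in list(two_way_scheme(), three_way_scheme(),
                 modulation_scheme(c(0, -1.5, -5), c(0.2, 0.5, 0.3)))) {
    parts <- apply_scheme(canonical, s)
    total <- sum(vapply(parts, function(b) sum(b$weights), 0))
    expect_equal(total, sum(canonical$weights), tolerance = 1e-12)
  }
})

test_that("range shifts recompute auto sigma but preserve explicit sigma", {
  parts <- apply_scheme(canonical, two_way_scheme())
  shifted <- parts[[2]]$peaks[[1]]
  expect_equal(shifted$nominal_range, 147)
  expect_equal(shifted$sigma, sqrt(range_straggling(147)^2 + 2.4^2))
  fixed <- weighted_beam(list(pristine_peak(150, sigma = 1.5)), 1)
  parts2 <- apply_scheme(fixed, two_way_scheme())
  expect_equal(parts2[[2]]$peaks[[1]]$sigma, 1.5)
})

test_that("a shift that pulls a peak below zero range is an error", {
  b <- weighted_beam(list(pristine_peak(2)), 1)
  expect_error(apply_scheme(b, two_way_scheme(3)), "non-positive")
})

test_that("mid-plateau dose is insensitive to the default two-way split", {
  md <- modulated_dose(canonical, two_way_scheme())
  mid <- which.min(abs(canonical$grid - mean(canonical$plateau)))
  expect_equal(md$physical$values[mid], canonical$physical$values[mid],
               tolerance = 0.01)
})

test_that("modulation reduces the biological dose at the unmodulated physical R90", {
  ref <- mean(canonical$physical$values[
    canonical$grid >= canonical$plateau[1] & canonical$grid <= canonical$plateau[2]])
  r90 <- range_at(canonical$physical, 0.9, ref)
  at_r90 <- function(curve) stats::approx(curve$depths, curve$values, r90)$y
  unmod_bio <- at_r90(canonical$biological)
  two <- modulated_dose(canonical, two_way_scheme())
  three <- modulated_dose(canonical, three_way_scheme())
  expect_lt(at_r90(two$biological), unmod_bio)
  expect_lt(at_r90(three$biological), unmod_bio)
})

test_that("smearing widens the distal 80-20 falloff, monotonically in delta", {
  ref <- mean(canonical$physical$values[
    canonical$grid >= canonical$plateau[1] & canonical$grid <= canonical$plateau[2]])
  falloff <- function(curve)
    range_at(curve, 0.2, ref) - range_at(curve, 0.8, ref)
  w0 <- falloff(canonical$physical)
  widths <- vapply(c(1, 3, 6), function(d)
    falloff(modulated_dose(canonical, two_way_scheme(d))$physical), 0)
  expect_true(all(widths > w0))
  expect_true(all(diff(widths) > 0))
})

test_that("terminal mean RBE is ordered three-way <= two-way <= unmodulated", {
  t0 <- terminal_mean_rbe(canonical)
  t2 <- terminal_mean_rbe(canonical, scheme = two_way_scheme())
  t3 <- terminal_mean_rbe(canonical, scheme = three_way_scheme())
  expect_lt(t2, t0)
  expect_lte(t3, t2)
})
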