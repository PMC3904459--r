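# canonical 4-peak, 6 mm, 150 mm beam shared across test files; the fit is
# deterministic so building it once is safe
canonical <- sobp()

# sum of squared plateau deviations for a weight vector, used by the
# local-optimality oracle
plateau_sse <- function(beam, w) {
  grid <- beam$grid
  A <- vapply(beam$peaks, function(p) {
    v <- rangemod::pristine_depth_dose(p, grid)$values
    v
  }, numeric(length(grid)))
  sel <- grid >= beam$plateau[1] & grid <= beam$plateau[2]
  sum((A[sel, , drop = FALSE] %*% w - beam$prescription)^2)
}

# synthetic monotone-falloff curve: flat plateau then smooth sigmoid drop
random_falloff_curve <- function(grid) {
  edge <- stats::runif(1, 0.4, 0.8) * max(grid)
  width <- stats::runif(1, 0.5, 5)
  level <- stats::runif(1, 50, 200)
  depth_dose(grid, level * stats::pnorm(edge, grid, width))
}
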