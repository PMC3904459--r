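#' Pristine Bragg peak
#'
#' Parameters of a single (un-spread) proton energy: the depth-dose of the
#' beam before any range modulation or plateau spreading.  The underlying
#' model is a Bragg--Kleeman stopping-power kernel,
#' \deqn{d_0(z; R) = (R - z)^{1/p - 1}, \quad 0 \le z < R,}
#' convolved with a Gaussian distribution of residual range (standard
#' deviation \code{sigma}) representing range straggling plus the energy
#' spread of the delivery system.  It is a simplified Bortfeld-style model
#' without nuclear-halo terms; sharp distal falloff of clinical magnitude is
#' what matters here, not entrance-region detail.
#'
#' When \code{sigma} is not supplied it follows the commissioning rule
#' \deqn{\sigma(R) = \sqrt{(0.012\,R^{0.935})^2 + \sigma_E^2},}
#' the standard range-straggling scaling plus the beam energy spread
#' \code{energy_spread} (mm) added in quadrature.  Peaks built this way
#' remember the rule, so a range shift (see \code{\link{apply_scheme}})
#' recomputes \code{sigma} from the shifted range.
#'
#' @param nominal_range depth in mm water-equivalent at which the
#'   straggling-free particle stops; must be positive.
#' @param sigma Gaussian range-spread standard deviation in mm
#'   (\eqn{\ge 0}); \code{NULL} (default) applies the rule above.
#' @param exponent Bragg--Kleeman power-law exponent \eqn{p > 1}
#'   (default 1.77, the standard value for protons in water).
#' @param energy_spread delivery-system energy spread in mm of range,
#'   used only when \code{sigma} is \code{NULL}; default 2.4 mm.
#'
#' @return An object of class \code{"pristine_peak"}.
#' @seealso \code{\link{pristine_depth_dose}}, \code{\link{sobp}}
#' @examples
#' pk <- pristine_peak(150)
#' pk$sigma                      # ~2.73 mm at 150 mm range
#' @export
pristine_peak <- function(nominal_range, sigma = NULL, exponent = 1.77,
                          energy_spread = 2.4) {
  if (!is.numeric(nominal_range) || length(nominal_range) != 1L ||
      !is.finite(nominal_range) || nominal_range <= 0)
    stop_validation("'nominal_range' must be a single positive number (mm)")
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 1)
    stop_validation("'exponent' must be > 1")
  auto <- is.null(sigma)
  if (auto) {
    if (!is.numeric(energy_spread) || energy_spread < 0)
      stop_validation("'energy_spread' must be >= 0 mm")
    sigma <- total_range_spread(nominal_range, energy_spread)
  } else {
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
      stop_validation("'sigma' must be a single number >= 0 (mm)")
  }
  structure(list(nominal_range = nominal_range, sigma = sigma,
                 exponent = exponent, sigma_auto = auto,
                 energy_spread = if (auto) energy_spread else NA_real_),
            class = "pristine_peak")
}

#' @export
print.pristine_peak <- function(x, ...) {
  cat(sprintf("Pristine Bragg peak: R = %.6g mm, sigma = %.4g mm%s, p = %.4g\n",
              x$nominal_range, x$sigma,
              if (isTRUE(x$sigma_auto)) " (auto)" else "", x$exponent))
  invisible(x)
}

#' Range-straggling width
#'
#' Standard deviation of the intrinsic range-straggling distribution for a
#' proton beam of the given range in water, \eqn{0.012\,R^{0.935}} mm.
#'
#' @param nominal_range range in mm water-equivalent.
#' @return straggling sigma in mm.
#' @export
range_straggling <- function(nominal_range) 0.012 * nominal_range^0.935

# straggling + delivery-system energy spread, in quadrature
total_range_spread <- function(nominal_range, energy_spread = 2.4) {
  sqrt(range_straggling(nominal_range)^2 + energy_spread^2)
}

#' Pristine depth-dose curve
#'
#' Evaluates the depth-dose of a pristine Bragg peak on a depth grid.  With
#' \code{sigma = 0} this is the bare Bragg--Kleeman kernel
#' \eqn{(R-z)^{1/p-1}}; otherwise the kernel is integrated against the
#' normal density of residual range \eqn{r} over
#' \eqn{[R - 6\sigma,\, R + 6\sigma]}.  The substitution \eqn{u = (r-z)^{1/p}}
#' removes the integrable singularity at \eqn{r = z}, leaving a smooth
#' integrand
#' \deqn{D(z) = p \int \varphi(z + u^p;\, R, \sigma)\, du}
#' evaluated by Gauss--Legendre quadrature.  The returned curve is
#' normalized so its maximum is 1; absolute dose is carried by beam weights.
#'
#' @param peak a \code{\link{pristine_peak}}.
#' @param grid depth grid in mm: strictly increasing, uniform, spacing
#'   \eqn{\le 0.5} mm, depths \eqn{\ge 0}.
#' @param nodes number of Gauss--Legendre quadrature nodes (default 64;
#'   halving the step, i.e. doubling \code{nodes}, changes the curve by
#'   less than 1e-4 everywhere at the default).
#'
#' @return A \code{\link{depth_dose}} curve with maximum value 1.
#' @examples
#' g <- seq(0, 180, 0.1)
#' dd <- pristine_depth_dose(pristine_peak(150), g)
#' dd$depths[which.max(dd$values)]   # peak sits just short of 150 mm
#' @export
pristine_depth_dose <- function(peak, grid, nodes = 64L) {
  check_peak(peak)
  check_grid(grid)
  v <- pristine_values(peak, grid, nodes)
  m <- max(v)
  if (m <= 0)
    stop_computation("grid does not cover any part of the peak (all dose zero)")
  depth_dose(grid, v / m)
}

# unnormalized kernel evaluation shared by pristine_depth_dose and compose
pristine_values <- function(peak, grid, nodes = 64L) {
  R <- peak$nominal_range
  p <- peak$exponent
  s <- peak$sigma
  if (s == 0) {
    v <- numeric(length(grid))
    in_range <- grid >= 0 & grid < R
    v[in_range] <- (R - grid[in_range])^(1 / p - 1)
    return(v)
  }
  a <- max(R - 6 * s, 0)
  b <- R + 6 * s
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  v <- numeric(length(grid))
  live <- grid < b
  z <- grid[live]
  lo <- pmax(a - z, 0)^(1 / p)
  hi <- (b - z)^(1 / p)
  # nodes x points matrices; u = lo + (hi-lo)*x, integrand phi(z + u^p)
  U <- outer(gl$x, hi - lo) + rep(lo, each = nodes)
  Z <- rep(z, each = nodes)
  E <- stats::dnorm(Z + U^p, mean = R, sd = s)
  dim(E) <- c(nodes, length(z))
  v[live] <- p * (hi - lo) * colSums(E * gl$w)
  v
}

#' Depth of maximum dose of a pristine peak
#'
#' Locates the maximum of the straggled pristine curve by argmax on a fine
#' dedicated grid around the nominal range (independent of any user grid),
#' so RBE centering and plateau bounds do not depend on the caller's grid
#' resolution.
#'
#' @param peak a \code{\link{pristine_peak}}.
#' @param step grid step in mm for the search (default 0.01).
#' @return depth of maximum in mm.
#' @export
peak_max_depth <- function(peak, step = 0.01) {
  check_peak(peak)
  R <- peak$nominal_range
  s <- peak$sigma
  if (s == 0) {
    # bare kernel increases monotonically up to R: the supremum is at R
    return(R)
  }
  g <- seq(max(R - 6 * s, 0), R + 2 * s, by = step)
  v <- pristine_values(peak, g)
  g[which.max(v)]
}

check_peak <- function(peak) {
  if (!inherits(peak, "pristine_peak"))
    stop_validation("expected a 'pristine_peak' object")
  invisible(peak)
}

check_grid <- function(grid, max_step = 0.5) {
  if (!is.numeric(grid) || length(grid) == 0L)
    stop_validation("depth grid must be a non-empty numeric vector")
  if (any(grid < 0))
    stop_validation("depths must be >= 0")
  if (length(grid) > 1L) {
    dz <- diff(grid)
    if (any(dz <= 0))
      stop_validation("depth grid must be strictly increasing")
    if (max(dz) - min(dz) > 1e-9 * max(dz))
      stop_validation("depth grid must be uniformly spaced")
    if (dz[1L] > max_step)
      stop_validation("depth grid spacing must be <= %.3g mm", max_step)
  }
  invisible(grid)
}
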