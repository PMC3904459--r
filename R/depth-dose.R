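#' Depth-dose curve
#'
#' The universal exchange object of the package: a strictly increasing,
#' uniformly spaced depth grid (mm water-equivalent) together with
#' non-negative relative dose values (arbitrary units).  The same container
#' carries dimensionless RBE profiles, in which case the values are RBE
#' rather than dose.
#'
#' @param depths numeric vector of depths in mm water-equivalent; strictly
#'   increasing with uniform spacing (relative tolerance 1e-9).
#' @param values numeric vector of relative dose (or RBE), same length as
#'   \code{depths}, all values \eqn{\ge 0}.
#'
#' @return An object of class \code{"depth_dose"}: a list with elements
#'   \code{depths} and \code{values}.
#' @examples
#' dd <- depth_dose(seq(0, 10, 0.5), exp(-seq(0, 10, 0.5)))
#' plot(dd)
#' @export
depth_dose <- function(depths, values) {
  depths <- as.numeric(depths)
  values <- as.numeric(values)
  if (length(depths) == 0L)
    stop_validation("depth-dose curve needs at least one grid point")
  if (length(depths) != length(values))
    stop_validation("'depths' and 'values' must have equal length")
  if (anyNA(depths) || anyNA(values))
    stop_validation("depth-dose curve must not contain NA")
  if (length(depths) > 1L) {
    dz <- diff(depths)
    if (any(dz <= 0))
      stop_validation("depths must be strictly increasing")
    if (max(dz) - min(dz) > 1e-9 * max(abs(dz)))
      stop_validation("depth grid must be uniformly spaced (relative tolerance 1e-9)")
  }
  if (any(values < 0))
    stop_validation("dose values must be non-negative")
  structure(list(depths = depths, values = values), class = "depth_dose")
}

#' @export
print.depth_dose <- function(x, ...) {
  n <- length(x$depths)
  cat(sprintf("Depth-dose curve: %d points, %.6g to %.6g mm (step %.6g mm)\n",
              n, x$depths[1L], x$depths[n],
              if (n > 1L) x$depths[2L] - x$depths[1L] else NA_real_))
  cat(sprintf("  values: max %.6g at %.6g mm\n",
              max(x$values), x$depths[which.max(x$values)]))
  invisible(x)
}

#' @export
as.data.frame.depth_dose <- function(x, ...) {
  data.frame(depth_mm = x$depths, dose = x$values)
}

#' @export
plot.depth_dose <- function(x, ..., xlab = "Depth [mm w.e.]",
                            ylab = "Relative dose [AU]", type = "l") {
  graphics::plot(x$depths, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# spacing of a depth_dose grid (uniform by construction)
grid_step <- function(curve) {
  if (length(curve$depths) < 2L) return(NA_real_)
  curve$depths[2L] - curve$depths[1L]
}

# classed conditions so the CLI can map validation vs computation failures
# onto distinct exit codes
stop_validation <- function(msg, ...) {
  stop(structure(class = c("rangemod_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1L))))
}

stop_computation <- function(msg, ..., class = character()) {
  stop(structure(class = c(class, "rangemod_computation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1L))))
}
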