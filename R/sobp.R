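#' Weighted beam
#'
#' A set of pristine Bragg peaks with non-negative weights: the delivery
#' description of a spread-out Bragg peak (SOBP) or of one component of a
#' range-modulated delivery.
#'
#' @param peaks list of \code{\link{pristine_peak}} objects.
#' @param weights numeric vector of non-negative weights, one per peak,
#'   at least one positive.
#' @param prescription plateau dose level in arbitrary units that the
#'   weights were solved for (default 100, so doses read as percentages).
#' @return An object of class \code{"weighted_beam"}.
#' @export
weighted_beam <- function(peaks, weights, prescription = 100) {
  if (!is.list(peaks) || length(peaks) == 0L)
    stop_validation("'peaks' must be a non-empty list of pristine_peak objects")
  lapply(peaks, check_peak)
  weights <- as.numeric(weights)
  if (length(weights) != length(peaks))
    stop_validation("one weight per peak required")
  if (anyNA(weights) || any(weights < 0))
    stop_validation("weights must be non-negative")
  if (all(weights == 0))
    stop_validation("at least one weight must be positive")
  structure(list(peaks = peaks, weights = weights,
                 prescription = prescription),
            class = "weighted_beam")
}

#' @export
print.weighted_beam <- function(x, ...) {
  cat(sprintf("Weighted proton beam: %d pristine peaks\n", length(x$peaks)))
  rng <- vapply(x$peaks, function(p) p$nominal_range, 0)
  print(data.frame(range_mm = rng, sigma_mm = vapply(x$peaks, function(p) p$sigma, 0),
                   weight = x$weights), row.names = FALSE)
  invisible(x)
}

#' Fit a spread-out Bragg peak
#'
#' Composes \code{n_peaks} equally spaced pristine Bragg peaks (deepest at
#' \code{distal_range}, each subsequent peak pulled back by \code{spacing})
#' and solves non-negative weights that flatten the physical-dose plateau at
#' the \code{prescription} level by non-negative least squares.  The plateau
#' is the interval between the straggled dose maxima of the shallowest and
#' deepest peaks, shrunk inward by \code{plateau_margin} at each end so edge
#' ripple does not dominate the fit.
#'
#' The returned object carries the solved beam, the depth grid, the
#' physical and RBE-weighted depth-dose curves, and the plateau interval,
#' and supports the usual modelling verbs: \code{coef} (weights),
#' \code{fitted}/\code{predict} (dose), \code{residuals} (plateau deviation
#' from prescription), \code{summary} (dose metrics), \code{plot}.
#'
#' @param distal_range nominal range in mm of the deepest peak (default
#'   150 mm, the canonical beam used throughout).
#' @param n_peaks number of pristine peaks (default 4).
#' @param spacing pull-back between adjacent peaks in mm (default 6, the
#'   pristine-peak spacing of a uniform-scanning delivery system).
#' @param plateau_margin inward margin in mm applied to both plateau ends
#'   (default 1).
#' @param prescription plateau dose target in arbitrary units (default 100).
#' @param grid_step depth grid step in mm (default 0.1).
#' @param grid_max deepest grid point in mm; default
#'   \code{distal_range + 30} so the distal tail is fully covered.
#' @param exponent,energy_spread,sigma passed to
#'   \code{\link{pristine_peak}} for every component.
#' @param rbe \code{\link{rbe_params}} used for the stored RBE-weighted
#'   curve and by \code{summary}.
#'
#' @return An object of class \code{c("sobp", "weighted_beam")} with
#'   elements \code{peaks}, \code{weights}, \code{prescription},
#'   \code{grid}, \code{physical}, \code{biological} (both
#'   \code{\link{depth_dose}}), \code{plateau} (length-2 interval),
#'   \code{peak_maxima}, \code{rbe}.
#' @examples
#' b <- sobp()                    # canonical 4-peak, 150 mm beam
#' coef(b)
#' summary(b)
#' @export
sobp <- function(distal_range = 150, n_peaks = 4, spacing = 6,
                 plateau_margin = 1, prescription = 100,
                 grid_step = 0.1, grid_max = distal_range + 30,
                 exponent = 1.77, energy_spread = 2.4, sigma = NULL,
                 rbe = rbe_params()) {
  if (n_peaks < 1)
    stop_validation("'n_peaks' must be >= 1")
  if (spacing <= 0)
    stop_validation("'spacing' must be > 0 mm")
  ranges <- distal_range - (seq_len(n_peaks) - 1) * spacing
  if (any(ranges <= 0))
    stop_validation("shallowest peak range would be <= 0; reduce n_peaks or spacing")
  peaks <- lapply(ranges, pristine_peak, sigma = sigma, exponent = exponent,
                  energy_spread = energy_spread)
  grid <- seq(0, grid_max, by = grid_step)
  check_grid(grid)

  maxima <- vapply(peaks, peak_max_depth, 0)
  if (n_peaks == 1L) {
    plateau <- c(maxima, maxima)       # degenerate: fit the peak itself
    w <- prescription                  # curves are max-normalized to 1
  } else {
    plateau <- c(min(maxima) + plateau_margin, max(maxima) - plateau_margin)
    if (plateau[1L] >= plateau[2L])
      stop_validation("plateau interval empty after margins; reduce 'plateau_margin'")
    w <- solve_weights(peaks, plateau, prescription, grid)
  }

  beam <- weighted_beam(peaks, w, prescription)
  phys <- compose(beam, grid)
  bio <- rbe_weighted_dose(beam, rbe, grid)
  structure(c(beam,
              list(grid = grid, physical = phys, biological = bio,
                   plateau = plateau, peak_maxima = maxima, rbe = rbe,
                   spec = list(distal_range = distal_range, n_peaks = n_peaks,
                               spacing = spacing, plateau_margin = plateau_margin,
                               grid_step = grid_step, grid_max = grid_max,
                               energy_spread = energy_spread))),
            class = c("sobp", "weighted_beam"))
}

#' Solve plateau weights by non-negative least squares
#'
#' Minimizes the sum of squared deviations of the composed dose from
#' \code{target} over the grid points inside \code{plateau}, subject to all
#' weights \eqn{\ge 0} (Lawson--Hanson NNLS via \code{pracma::lsqnonneg}).
#' Duplicate peaks make the design singular; they are collapsed before
#' solving and the solved weight of each duplicate group is split equally
#' among its members, which selects the minimum-Euclidean-norm minimizer
#' (with a warning).
#'
#' @param peaks list of \code{\link{pristine_peak}}s.
#' @param plateau length-2 numeric interval (mm) over which to flatten.
#' @param target plateau dose level.
#' @param grid depth grid; at least 10 grid points must fall inside
#'   \code{plateau}.
#' @return numeric vector of non-negative weights.
#' @export
solve_weights <- function(peaks, plateau, target, grid) {
  lapply(peaks, check_peak)
  check_grid(grid)
  sel <- grid >= plateau[1L] & grid <= plateau[2L]
  if (sum(sel) < 10L)
    stop_validation("need at least 10 grid points inside the plateau (got %d)", sum(sel))
  A <- vapply(peaks, function(p) {
    v <- pristine_values(p, grid)
    v / max(v)
  }, numeric(length(grid)))
  key <- vapply(peaks, function(p)
    sprintf("%.12g|%.12g|%.12g", p$nominal_range, p$sigma, p$exponent), "")
  uk <- unique(key)
  if (length(uk) < length(key)) {
    warning("duplicate pristine peaks: design is singular; returning the ",
            "minimum-norm weight split", call. = FALSE)
    Au <- vapply(uk, function(k) A[, match(k, key)], numeric(length(grid)))
    wu <- pracma::lsqnonneg(Au[sel, , drop = FALSE], rep(target, sum(sel)))$x
    w <- numeric(length(key))
    for (i in seq_along(uk)) {
      members <- which(key == uk[i])
      w[members] <- wu[i] / length(members)
    }
    return(w)
  }
  pracma::lsqnonneg(A[sel, , drop = FALSE], rep(target, sum(sel)))$x
}

#' Compose the physical depth-dose of a weighted beam
#'
#' Pointwise weighted sum of the (max-normalized) pristine curves of the
#' beam's components; linear in the weights.
#'
#' @param beam a \code{\link{weighted_beam}} (or \code{\link{sobp}}).
#' @param grid depth grid in mm.
#' @return A \code{\link{depth_dose}} curve.
#' @export
compose <- function(beam, grid) {
  check_beam(beam)
  check_grid(grid)
  v <- numeric(length(grid))
  for (k in seq_along(beam$peaks)) {
    pv <- pristine_values(beam$peaks[[k]], grid)
    v <- v + beam$weights[k] * pv / max(pv)
  }
  depth_dose(grid, v)
}

check_beam <- function(beam) {
  if (!inherits(beam, "weighted_beam"))
    stop_validation("expected a 'weighted_beam' (or 'sobp') object")
  invisible(beam)
}

# plateau interval for a plain weighted_beam (sobp objects store theirs)
beam_plateau <- function(beam, margin = 1) {
  if (!is.null(beam$plateau)) return(beam$plateau)
  live <- beam$weights > 0
  maxima <- vapply(beam$peaks[live], peak_max_depth, 0)
  if (length(maxima) == 1L) return(c(maxima, maxima))
  c(min(maxima) + margin, max(maxima) - margin)
}

#' @export
coef.sobp <- function(object, ...) {
  stats::setNames(object$weights,
                  sprintf("R%.4gmm", vapply(object$peaks, function(p) p$nominal_range, 0)))
}

#' @export
fitted.sobp <- function(object, ...) object$physical

#' @export
residuals.sobp <- function(object, ...) {
  sel <- object$grid >= object$plateau[1L] & object$grid <= object$plateau[2L]
  object$physical$values[sel] - object$prescription
}

#' Predict dose at arbitrary depths
#'
#' Evaluates the fitted beam's physical or RBE-weighted dose at new depths
#' by re-composing the pristine curves (not by interpolating the stored
#' grid).
#'
#' @param object an \code{\link{sobp}} fit.
#' @param depths numeric vector of depths in mm; defaults to the fit grid.
#' @param type \code{"physical"} or \code{"biological"}.
#' @param ... unused.
#' @return numeric vector of dose values at \code{depths}.
#' @export
predict.sobp <- function(object, depths = NULL, type = c("physical", "biological"),
                         ...) {
  type <- match.arg(type)
  if (is.null(depths))
    return(switch(type, physical = object$physical$values,
                  biological = object$biological$values))
  depths <- as.numeric(depths)
  if (any(depths < 0)) stop_validation("depths must be >= 0")
  v <- numeric(length(depths))
  for (k in seq_along(object$peaks)) {
    pk <- object$peaks[[k]]
    pv <- pristine_values(pk, sort(depths))[order(order(depths))]
    # normalize against the peak's true maximum, not the max over 'depths'
    ref <- pristine_values(pk, seq(max(pk$nominal_range - 6 * pk$sigma - 1, 0),
                                   pk$nominal_range + 6 * pk$sigma, by = 0.01))
    pv <- pv / max(ref)
    if (type == "biological") {
      prof <- rbe_values(depths, peak_max_depth(pk), object$rbe)
      pv <- pv * prof
    }
    v <- v + object$weights[k] * pv
  }
  v
}

#' @export
print.sobp <- function(x, ...) {
  cat(sprintf("Spread-out Bragg peak fit: %d peaks, distal range %.6g mm, spacing %.4g mm\n",
              length(x$peaks), x$spec$distal_range, x$spec$spacing))
  cat(sprintf("  plateau [%.4g, %.4g] mm, prescription %.6g AU\n",
              x$plateau[1L], x$plateau[2L], x$prescription))
  cat("  weights:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.sobp <- function(object, ...) {
  rep <- beam_metrics(object, params = object$rbe)
  out <- list(fit = object, metrics = rep)
  class(out) <- "summary.sobp"
  out
}

#' @export
print.summary.sobp <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$metrics)
  invisible(x)
}

#' Plot an SOBP fit
#'
#' Draws the physical and RBE-weighted SOBP, the weighted pristine
#' components, and the plateau interval.
#'
#' @param x an \code{\link{sobp}} fit.
#' @param components draw the weighted pristine curves (default TRUE).
#' @param ... passed to \code{plot}.
#' @export
plot.sobp <- function(x, components = TRUE, ...) {
  ymax <- max(x$biological$values)
  graphics::plot(x$grid, x$physical$values, type = "l", lwd = 2,
                 xlab = "Depth [mm w.e.]", ylab = "Relative dose [AU]",
                 ylim = c(0, 1.05 * ymax), ...)
  graphics::lines(x$grid, x$biological$values, lwd = 2, col = "firebrick")
  if (components) {
    for (k in seq_along(x$peaks)) {
      pv <- pristine_values(x$peaks[[k]], x$grid)
      graphics::lines(x$grid, x$weights[k] * pv / max(pv), lty = 3, col = "grey40")
    }
  }
  graphics::abline(v = x$plateau, lty = 2, col = "grey60")
  graphics::abline(h = x$prescription, lty = 2, col = "grey60")
  graphics::legend("topleft", bty = "n", lwd = 2, col = c("black", "firebrick"),
                   legend = c("physical", "RBE-weighted"))
  invisible(x)
}
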