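#' Plateau flatness
#'
#' Relative peak-to-trough variation of a depth-dose curve over a region:
#' \eqn{100 (\max - \min)/\mathrm{mean}} in percent, evaluated on the grid
#' points inside the region.  Scale-invariant and non-negative.
#'
#' @param curve a \code{\link{depth_dose}}.
#' @param region length-2 depth interval in mm containing at least 10 grid
#'   points.
#' @return flatness in percent.
#' @examples
#' g <- seq(0, 10, 0.5)
#' flatness(depth_dose(g, rep(100, length(g))), c(0, 10))   # 0
#' @export
flatness <- function(curve, region) {
  sel <- curve$depths >= region[1L] & curve$depths <= region[2L]
  if (sum(sel) < 10L)
    stop_validation("flatness region must contain at least 10 grid points (got %d)",
                    sum(sel))
  v <- curve$values[sel]
  100 * (max(v) - min(v)) / mean(v)
}

#' Distal range at a dose fraction
#'
#' Deepest depth at which the curve crosses \code{fraction * reference} on
#' its distal (falling) side, by linear interpolation between the
#' bracketing grid points.  With \code{fraction = 0.9} and the plateau
#' level as reference this is the clinical R90.
#'
#' @param curve a \code{\link{depth_dose}}.
#' @param fraction dose fraction in (0, 1).
#' @param reference reference dose level (e.g. the mean plateau dose).
#' @return crossing depth in mm.  If the curve never reaches the threshold,
#'   or never falls below it again, a condition of class
#'   \code{"rangemod_range_undefined"} is signalled.
#' @examples
#' g <- seq(0, 100, 0.5)
#' ramp <- depth_dose(g, pmin(100, pmax(0, 100 * (60 - g) / 10)))
#' range_at(ramp, 0.5, 100)   # 55
#' @export
range_at <- function(curve, fraction, reference) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_validation("'fraction' must lie in (0, 1)")
  if (!is.numeric(reference) || reference <= 0)
    stop_validation("'reference' must be > 0")
  thr <- fraction * reference
  v <- curve$values
  z <- curve$depths
  idx <- which(v >= thr)
  if (length(idx) == 0L || max(idx) == length(v))
    stop_computation("range undefined: curve does not cross %.6g on its distal side",
                     thr, class = "rangemod_range_undefined")
  i <- max(idx)
  z[i] + (thr - v[i]) * (z[i + 1L] - z[i]) / (v[i + 1L] - v[i])
}

#' Biologically effective range extension
#'
#' Difference between the distal 90\% crossing of the RBE-weighted curve
#' (reference: baseline times the mean physical plateau dose, so the
#' extension measures the distal RBE ramp and not the uniform baseline
#' scaling) and that of the physical curve (reference: mean physical
#' plateau dose).  For the default beam and model this is the familiar
#' 1--2 mm extension of effective proton range.
#'
#' @param beam a \code{\link{weighted_beam}} or \code{\link{sobp}}.
#' @param params \code{\link{rbe_params}}.
#' @param grid depth grid; defaults to the fit grid for \code{sobp}
#'   objects.
#' @param fraction falloff fraction defining "range" (default 0.9, i.e.
#'   R90; use 0.8 for R80).
#' @return range extension in mm (0 when \code{saturation = 0}).
#' @export
bio_range_extension <- function(beam, params = rbe_params(), grid = NULL,
                                fraction = 0.9) {
  if (is.null(grid)) grid <- beam$grid
  if (is.null(grid)) stop_validation("'grid' is required for a plain weighted_beam")
  phys <- compose(beam, grid)
  bio <- rbe_weighted_dose(beam, params, grid)
  ref <- plateau_reference(beam, phys)
  range_at(bio, fraction, params$baseline * ref) - range_at(phys, fraction, ref)
}

#' Terminal-window mean RBE
#'
#' Dose-weighted mean of \eqn{D_{bio}/D_{phys}} (weights: physical dose,
#' i.e. the ratio of integrals) over a window of half-width \code{window}
#' mm centered on the evaluated delivery's own physical R90 -- the terminal
#' few millimetres of that SOBP.  The reference level defining R90 is
#' always the unmodulated plateau mean, so modulated and unmodulated
#' deliveries are compared against the same prescription.  Range
#' modulation pulls the terminal window shallower and fills it with
#' lower-RBE dose, which is how it dilutes the distal hotspot.
#'
#' @param beam a \code{\link{weighted_beam}} or \code{\link{sobp}}.
#' @param params \code{\link{rbe_params}}.
#' @param scheme a \code{\link{modulation_scheme}} or \code{NULL} for the
#'   unmodulated beam.
#' @param grid depth grid; defaults to the fit grid for \code{sobp}s.
#' @param window half-width of the terminal window in mm (default 5).
#' @return dimensionless mean RBE, bounded in
#'   \eqn{[b,\ b(1+a)]}; exactly \code{baseline} when
#'   \code{saturation = 0}.
#' @export
terminal_mean_rbe <- function(beam, params = rbe_params(), scheme = NULL,
                              grid = NULL, window = 5) {
  if (is.null(grid)) grid <- beam$grid
  if (is.null(grid)) stop_validation("'grid' is required for a plain weighted_beam")
  if (window <= 0) stop_validation("'window' must be > 0 mm")
  unmod_phys <- compose(beam, grid)
  ref <- plateau_reference(beam, unmod_phys)
  if (is.null(scheme)) {
    phys <- unmod_phys
    bio <- rbe_weighted_dose(beam, params, grid)
  } else {
    md <- modulated_dose(beam, scheme, params, grid)
    phys <- md$physical
    bio <- md$biological
  }
  r90 <- range_at(phys, 0.9, ref)
  sel <- grid >= r90 - window & grid <= r90 + window
  denom <- sum(phys$values[sel])
  if (denom <= 0)
    stop_validation("zero physical dose in the terminal window")
  sum(bio$values[sel]) / denom
}

# mean physical dose over the beam's plateau; degenerate plateau (single
# peak) falls back to the dose at the peak maximum
plateau_reference <- function(beam, phys) {
  pl <- beam_plateau(beam)
  sel <- phys$depths >= pl[1L] & phys$depths <= pl[2L]
  if (!any(sel)) {
    i <- which.min(abs(phys$depths - pl[1L]))
    return(phys$values[i])
  }
  mean(phys$values[sel])
}

#' Dose metrics report for a delivery
#'
#' Computes the package's full metric set for one delivery (a beam, with or
#' without a range-modulation scheme): plateau flatness of the physical and
#' RBE-weighted curves, physical and biological R90, their difference (the
#' biologically effective range extension), the distal biological hotspot
#' ratio (peak RBE-weighted dose beyond the plateau relative to the
#' baseline-scaled plateau level), the terminal-window mean RBE, and the
#' integral physical dose beyond the physical R90 and 2 and 5 mm deeper
#' (AU x mm).  Reference levels (plateau interval and mean plateau dose)
#' always come from the unmodulated beam so modulated deliveries are
#' measured against the same prescription.
#'
#' @param beam a \code{\link{weighted_beam}} or \code{\link{sobp}}.
#' @param params \code{\link{rbe_params}}.
#' @param scheme a \code{\link{modulation_scheme}} or \code{NULL}.
#' @param grid depth grid; defaults to the fit grid for \code{sobp}s.
#' @param window terminal-window half-width in mm (default 5).
#' @param fraction falloff fraction defining "range" (default 0.9).
#' @return An object of class \code{"metrics_report"}: a list of named
#'   scalar metrics plus \code{dose_beyond} (named numeric vector).
#' @examples
#' b <- sobp()
#' beam_metrics(b)
#' beam_metrics(b, scheme = two_way_scheme())
#' @export
beam_metrics <- function(beam, params = rbe_params(), scheme = NULL,
                         grid = NULL, window = 5, fraction = 0.9) {
  if (is.null(grid)) grid <- beam$grid
  if (is.null(grid)) stop_validation("'grid' is required for a plain weighted_beam")
  unmod_phys <- compose(beam, grid)
  pl <- beam_plateau(beam)
  ref <- plateau_reference(beam, unmod_phys)
  if (is.null(scheme)) {
    phys <- unmod_phys
    bio <- rbe_weighted_dose(beam, params, grid)
  } else {
    md <- modulated_dose(beam, scheme, params, grid)
    phys <- md$physical
    bio <- md$biological
  }
  r90p <- tryCatch(range_at(phys, fraction, ref), rangemod_range_undefined = function(e) NA_real_)
  r90b <- tryCatch(range_at(bio, fraction, params$baseline * ref),
                   rangemod_range_undefined = function(e) NA_real_)
  distal_sel <- grid >= pl[2L]
  hotspot <- max(bio$values[distal_sel]) / (params$baseline * ref)
  tmr <- terminal_mean_rbe(beam, params, scheme, grid, window)
  dz <- grid_step(phys)
  beyond <- function(d) if (is.na(d)) NA_real_ else sum(phys$values[grid >= d]) * dz
  rep <- list(
    flatness_physical = flatness(phys, pl),
    flatness_biological = flatness(bio, pl),
    r90_physical = r90p,
    r90_biological = r90b,
    range_extension = r90b - r90p,
    distal_hotspot_ratio = hotspot,
    terminal_mean_rbe = tmr,
    dose_beyond = c(r90 = beyond(r90p), r90plus2 = beyond(r90p + 2),
                    r90plus5 = beyond(r90p + 5)),
    window_mm = window, fraction = fraction,
    scheme = if (is.null(scheme)) "none" else
      paste0(length(scheme$shifts), "-way")
  )
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dose metrics (%s delivery):\n", x$scheme))
  cat(sprintf("  plateau flatness     physical %6.3f %%   RBE-weighted %6.3f %%\n",
              x$flatness_physical, x$flatness_biological))
  cat(sprintf("  R%.0f                  physical %7.2f mm  biological %7.2f mm\n",
              100 * x$fraction, x$r90_physical, x$r90_biological))
  cat(sprintf("  range extension      %.3f mm\n", x$range_extension))
  cat(sprintf("  distal hotspot ratio %.4f\n", x$distal_hotspot_ratio))
  cat(sprintf("  terminal mean RBE    %.4f  (window +/- %g mm)\n",
              x$terminal_mean_rbe, x$window_mm))
  cat(sprintf("  dose beyond R%.0f / +2 / +5 mm: %.2f / %.2f / %.2f AU.mm\n",
              100 * x$fraction, x$dose_beyond[["r90"]],
              x$dose_beyond[["r90plus2"]], x$dose_beyond[["r90plus5"]]))
  invisible(x)
}

# scalar metrics compared by compare_metrics, and whether lower is better
.metric_directions <- c(
  flatness_physical = "lower", flatness_biological = "lower",
  r90_physical = "neutral", r90_biological = "neutral",
  range_extension = "lower", distal_hotspot_ratio = "lower",
  terminal_mean_rbe = "lower")

#' Compare two metric reports
#'
#' Per-metric deltas (\code{modulated - unmodulated}) with a flag:
#' \code{unchanged} when the delta is within tolerance, otherwise
#' \code{improved}/\code{worsened} for metrics with a preferred direction
#' (flatness, range extension, hotspot ratio, terminal mean RBE: lower is
#' better) and \code{changed} for the neutral range metrics.
#'
#' @param unmod,mod \code{\link{beam_metrics}} reports for the same beam
#'   prescription.
#' @param tol equality tolerance (default 1e-6).
#' @return A data frame of class \code{"metrics_comparison"} with columns
#'   \code{metric}, \code{unmodulated}, \code{modulated}, \code{delta},
#'   \code{flag}.
#' @export
compare_metrics <- function(unmod, mod, tol = 1e-6) {
  if (!inherits(unmod, "metrics_report") || !inherits(mod, "metrics_report"))
    stop_validation("expected two 'metrics_report' objects")
  metrics <- names(.metric_directions)
  a <- vapply(metrics, function(m) unmod[[m]], 0)
  b <- vapply(metrics, function(m) mod[[m]], 0)
  delta <- b - a
  flag <- vapply(metrics, function(m) {
    d <- b[[m]] - a[[m]]
    if (is.na(d)) return("undefined")
    if (abs(d) <= tol) return("unchanged")
    if (.metric_directions[[m]] == "neutral") return("changed")
    if (d < 0) "improved" else "worsened"
  }, "")
  out <- data.frame(metric = metrics, unmodulated = a, modulated = b,
                    delta = delta, flag = flag, row.names = NULL)
  class(out) <- c("metrics_comparison", "data.frame")
  out
}
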