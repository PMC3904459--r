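#' Read a depth-dose curve from delimited text
#'
#' Two columns, depth in mm then relative dose, separated by comma or tab.
#' An optional single header row is skipped; lines starting with \code{#}
#' are comments.  Parse failures (ragged or non-numeric rows) name the
#' offending line; the resulting curve must have strictly increasing,
#' uniformly spaced depths and non-negative dose.
#'
#' @param path file path.
#' @return A \code{\link{depth_dose}} curve.
#' @seealso \code{\link{write_curve}}
#' @export
read_curve <- function(path) {
  if (!file.exists(path))
    stop_validation("curve file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop_validation("no data rows in %s", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(parts[[1L]])))
  if (length(parts[[1L]]) == 2L && anyNA(first)) {
    # header row
    parts <- parts[-1L]
    lineno <- lineno[-1L]
    if (length(parts) == 0L) stop_validation("no data rows in %s", path)
  }
  n <- lengths(parts)
  if (any(n != 2L))
    stop_validation("parse error in %s, line %d: expected 2 fields, got %d",
                    path, lineno[which(n != 2L)[1L]], n[n != 2L][1L])
  m <- vapply(parts, function(p) suppressWarnings(as.numeric(trimws(p))),
              numeric(2L))
  bad <- which(colSums(is.na(m)) > 0L)
  if (length(bad))
    stop_validation("parse error in %s, line %d: non-numeric value", path,
                    lineno[bad[1L]])
  tryCatch(depth_dose(m[1L, ], m[2L, ]),
           rangemod_validation_error = function(e)
             stop_validation("invalid curve in %s: %s", path, conditionMessage(e)))
}

#' Write a depth-dose curve as delimited text
#'
#' Comma-separated, header \code{depth_mm,dose}, full double precision so
#' \code{read_curve(write_curve(x))} reproduces the curve to better than
#' 1e-12.
#'
#' @param curve a \code{\link{depth_dose}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "depth_dose"))
    stop_validation("expected a 'depth_dose' object")
  lines <- c("depth_mm,dose",
             sprintf("%.17g,%.17g", curve$depths, curve$values))
  writeLines(lines, path)
  invisible(path)
}

#' Write a metrics report as a key-value record
#'
#' Machine-parseable \code{key = value} lines in a fixed key order, units
#' embedded in the key names.  Undefined ranges are written as the sentinel
#' token \code{undefined}, never as a number.  Identical reports produce
#' byte-identical files.
#'
#' @param report a \code{\link{beam_metrics}} report.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_report}}
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "metrics_report"))
    stop_validation("expected a 'metrics_report' object")
  fmt <- function(x) if (is.na(x)) "undefined" else sprintf("%.17g", x)
  lines <- c(
    sprintf("scheme = %s", report$scheme),
    sprintf("flatness_physical_pct = %s", fmt(report$flatness_physical)),
    sprintf("flatness_biological_pct = %s", fmt(report$flatness_biological)),
    sprintf("r90_physical_mm = %s", fmt(report$r90_physical)),
    sprintf("r90_biological_mm = %s", fmt(report$r90_biological)),
    sprintf("range_extension_mm = %s", fmt(report$range_extension)),
    sprintf("distal_hotspot_ratio = %s", fmt(report$distal_hotspot_ratio)),
    sprintf("terminal_mean_rbe = %s", fmt(report$terminal_mean_rbe)),
    sprintf("dose_beyond_r90_au_mm = %s", fmt(report$dose_beyond[["r90"]])),
    sprintf("dose_beyond_r90plus2_au_mm = %s", fmt(report$dose_beyond[["r90plus2"]])),
    sprintf("dose_beyond_r90plus5_au_mm = %s", fmt(report$dose_beyond[["r90plus5"]])),
    sprintf("window_mm = %s", fmt(report$window_mm)),
    sprintf("fraction = %s", fmt(report$fraction)))
  con <- file(path, open = "wb")     # fixed EOL for byte-identical output
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read back a metrics report record
#'
#' @param path file written by \code{\link{write_report}}.
#' @return named list of values (\code{NA} for the \code{undefined}
#'   sentinel, character for \code{scheme}).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_validation("report file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^([a-z0-9_]+) = (.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop_validation("parse error in %s, line %d", path, bad[1L])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  out <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "scheme") return(vals[i])
    if (vals[i] == "undefined") return(NA_real_)
    as.numeric(vals[i])
  })
  stats::setNames(out, keys)
}

#' Canonical fixture beams
#'
#' Deterministic set of reference deliveries used in examples and tests:
#' the canonical four-peak, 6 mm-spacing, 150 mm SOBP; the same beam with
#' the default two-way (0/-3 mm) and three-way (0/-2/-4 mm) schemes; and a
#' single pristine peak.  Also returns the matching run configuration.
#'
#' @return Named list with elements \code{fig_sobp} (an \code{\link{sobp}}),
#'   \code{fig_twoway} and \code{fig_threeway} (lists with \code{beam} and
#'   \code{scheme}), \code{single_peak} (a \code{\link{weighted_beam}}),
#'   and \code{config} (the default run-configuration list).
#' @export
fixture_beams <- function() {
  base <- sobp(distal_range = 150, n_peaks = 4, spacing = 6)
  single <- sobp(distal_range = 150, n_peaks = 1)
  list(
    fig_sobp = base,
    fig_twoway = list(beam = base, scheme = two_way_scheme()),
    fig_threeway = list(beam = base, scheme = three_way_scheme()),
    single_peak = single,
    config = default_config())
}

# ---- run configuration -----------------------------------------------------

default_config <- function() {
  list(
    sobp = list(distal_range = 150, n_peaks = 4, spacing = 6,
                plateau_margin = 1, prescription = 100, energy_spread = 2.4),
    rbe = list(baseline = 1.1, saturation = 0.35, length = 2),
    scheme = list(name = "none", delta = 3, step = 2, direction = "pullback"),
    grid = list(min = 0, max = 180, step = 0.1),
    output = list(dir = "."))
}

.config_schema <- list(
  sobp = c("distal_range", "n_peaks", "spacing", "plateau_margin",
           "prescription", "energy_spread", "sigma", "exponent"),
  rbe = c("baseline", "saturation", "length"),
  scheme = c("name", "delta", "step", "direction"),
  grid = c("min", "max", "step"),
  output = c("dir"))

#' Read and validate a run configuration
#'
#' YAML file with the top-level sections \code{sobp}, \code{rbe},
#' \code{scheme}, \code{grid} and \code{output}; unknown sections or keys
#' are rejected.  Missing keys take the package defaults.
#'
#' @param path YAML file path, or \code{NULL} for the defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop_validation("config must be a YAML mapping")
  unknown <- setdiff(names(user), names(.config_schema))
  if (length(unknown))
    stop_validation("unknown config section(s): %s", paste(unknown, collapse = ", "))
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop_validation("unknown key(s) in section '%s': %s", sec,
                      paste(bad, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  if (!cfg$scheme$name %in% c("none", "two_way", "three_way"))
    stop_validation("scheme name must be one of none, two_way, three_way")
  if (cfg$grid$step <= 0 || cfg$grid$step > 0.5)
    stop_validation("grid step must be in (0, 0.5] mm")
  cfg
}

# build the model objects a config describes; shared by CLI subcommands
config_objects <- function(cfg) {
  s <- cfg$sobp
  beam <- sobp(distal_range = s$distal_range, n_peaks = s$n_peaks,
               spacing = s$spacing, plateau_margin = s$plateau_margin,
               prescription = s$prescription,
               grid_step = cfg$grid$step, grid_max = cfg$grid$max,
               energy_spread = s$energy_spread,
               sigma = s$sigma,
               exponent = if (is.null(s$exponent)) 1.77 else s$exponent,
               rbe = rbe_params(cfg$rbe$baseline, cfg$rbe$saturation,
                                cfg$rbe$length))
  scheme <- switch(cfg$scheme$name,
                   none = NULL,
                   two_way = two_way_scheme(cfg$scheme$delta,
                                            cfg$scheme$direction),
                   three_way = three_way_scheme(cfg$scheme$step,
                                                cfg$scheme$direction))
  list(beam = beam, scheme = scheme,
       rbe = rbe_params(cfg$rbe$baseline, cfg$rbe$saturation, cfg$rbe$length))
}
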