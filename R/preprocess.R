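#' Normalize a raw TGA trace to its dry reference mass
#'
#' Divides the mass column by the reference mass, taken as the mass at the
#' end of the drying hold (the last recorded point at or below `t_start`).
#' Water removed during the hold therefore does not enter the normalized
#' curve, and traces of different initial mass become comparable. Points
#' below `t_start` are trimmed (the hold itself collapses onto the ramp start
#' temperature).
#'
#' @param trace a `tga_trace` (columns `time_min`, `temperature_C`,
#'   `mass_mg`).
#' @param t_start analysis window start in degC (default 105).
#' @return the trace with `mass_mg` replaced by normalized mass; attributes
#'   `reference_mass_mg` and `normalized = TRUE` record the operation.
#' @export
normalize_trace <- function(trace, t_start = 105) {
  stopifnot(is.data.frame(trace),
            all(c("time_min", "temperature_C", "mass_mg") %in% names(trace)))
  idx <- which(trace$temperature_C <= t_start + 1e-9)
  if (!length(idx))
    stop("trace has no point at or below the hold end (", t_start, " degC)")
  ref <- trace$mass_mg[max(idx)]
  if (!is.finite(ref) || ref <= 0)
    stop("reference mass must be positive, got ", ref)
  keep <- trace$temperature_C >= t_start - 1e-9
  if (sum(keep) < 2) stop("fewer than 2 points in the analysis window")
  out <- trace[keep, , drop = FALSE]
  out$mass_mg <- out$mass_mg / ref
  rownames(out) <- NULL
  structure(out, sample_id = attr(trace, "sample_id"),
            reference_mass_mg = ref, normalized = TRUE,
            class = c("tga_trace", "data.frame"))
}

#' Differentiate a normalized trace into raw DTG samples
#'
#' Computes the mass-loss rate `-dm/dT` by central differences on the
#' temperature axis (one-sided at the ends), so a positive rate means mass
#' loss. Points sharing a temperature (e.g. the isothermal hold) are first
#' collapsed by averaging their masses, since a derivative with respect to
#' temperature is undefined there.
#'
#' @param trace a normalized `tga_trace` (see [normalize_trace()]).
#' @return data frame with columns `temperature_C` and `rate` (per degC).
#' @export
differentiate <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (!isTRUE(attr(trace, "normalized")))
    stop("differentiate() expects a normalized trace; run normalize_trace() first")
  temp <- trace$temperature_C
  mass <- trace$mass_mg
  if (is.unsorted(temp)) stop("temperatures must be non-decreasing on the ramp")
  ut <- unique(temp)
  if (length(ut) < length(temp))
    mass <- vapply(ut, function(t) mean(mass[temp == t]), numeric(1))
  temp <- ut
  n <- length(temp)
  if (n < 2) stop("need at least 2 distinct temperatures to differentiate")
  rate <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- -(mass[i + 1] - mass[i - 1]) / (temp[i + 1] - temp[i - 1])
  }
  rate[1] <- -(mass[2] - mass[1]) / (temp[2] - temp[1])
  rate[n] <- -(mass[n] - mass[n - 1]) / (temp[n] - temp[n - 1])
  out <- data.frame(temperature_C = temp, rate = rate)
  attr(out, "sample_id") <- attr(trace, "sample_id")
  out
}

#' Interpolate raw DTG samples onto a uniform grid
#'
#' Linear interpolation onto the grid temperatures, the step that puts every
#' sample on identical temperature points. The raw samples must span the
#' grid, up to a configurable extrapolation margin at each edge (within the
#' margin the nearest value is carried over).
#'
#' @param raw data frame with `temperature_C` and `rate` columns (as from
#'   [differentiate()]).
#' @param grid a [grid_spec()].
#' @param margin allowed extrapolation distance in degC at each grid edge.
#' @return a [dtg_curve()] of length `grid$count`.
#' @export
interpolate_to_grid <- function(raw, grid, margin = 0.5) {
  stopifnot(is.data.frame(raw), inherits(grid, "grid_spec"))
  tmin <- min(raw$temperature_C); tmax <- max(raw$temperature_C)
  if (tmin > grid$start + margin)
    stop("data start at ", tmin, " degC but the grid starts at ", grid$start,
         " degC: lower grid end not covered")
  if (tmax < grid$stop - margin)
    stop("data end at ", tmax, " degC but the grid stops at ", grid$stop,
         " degC: upper grid end not covered")
  vals <- stats::approx(raw$temperature_C, raw$rate,
                        xout = grid_temperatures(grid), rule = 2,
                        ties = "ordered")$y
  dtg_curve(attr(raw, "sample_id") %||% "sample", grid, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess a raw trace into a gridded DTG curve
#'
#' Convenience wrapper: [normalize_trace()], [differentiate()],
#' [interpolate_to_grid()] in sequence.
#'
#' @inheritParams normalize_trace
#' @inheritParams interpolate_to_grid
#' @return a [dtg_curve()].
#' @export
preprocess_trace <- function(trace, grid, t_start = grid$start, margin = 0.5) {
  interpolate_to_grid(differentiate(normalize_trace(trace, t_start)),
                      grid, margin)
}

#' Normalized root-mean-square difference between two DTG curves
#'
#' Repeatability measure for replicate runs: the RMS difference between the
#' two curves divided by the range of the first (reference) curve, in
#' percent. The normalization is asymmetric by convention -- the first
#' argument is the reference trial.
#'
#' @param ref,other `dtg_curve`s on identical grids.
#' @return NRMSE in percent (non-negative).
#' @export
compute_nrmse <- function(ref, other) {
  stopifnot(inherits(ref, "dtg_curve"), inherits(other, "dtg_curve"))
  if (!same_grid(ref$grid, other$grid)) stop("curves must share a grid")
  rng <- max(ref$rate) - min(ref$rate)
  if (rng <= 0) stop("reference curve has zero range; NRMSE undefined")
  100 * sqrt(mean((ref$rate - other$rate)^2)) / rng
}
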