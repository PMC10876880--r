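#' Define a chemical component for the synthetic generator
#'
#' A component couples a content distribution (how much of it samples contain)
#' to a set of signal windows (where it imprints on the DTG curve). Contents
#' are drawn from a truncated normal; each signal window adds a Gaussian peak
#' to the mass-loss rate, scaled linearly by the sample's content.
#'
#' @param name component label, e.g. `"Reducing sugar"`.
#' @param unit one of `"%"`, `"mg/g"`, `"pH-unit"`.
#' @param dist_mean,dist_sd mean and standard deviation of the content
#'   distribution, in `unit`. `dist_sd = 0` gives a degenerate (constant)
#'   component.
#' @param bounds length-2 numeric `(lo, hi)`; contents are truncated to this
#'   range after sampling.
#' @param signal_windows data frame with columns `t_lo`, `t_hi` (window edges
#'   in degC), `amplitude` (peak mass-loss rate per unit content, in
#'   1/degC per `unit`) and `width` (Gaussian standard deviation in degC).
#'   The peak is centred at the window midpoint.
#' @return object of class `component_def`.
#' @export
component_def <- function(name, unit, dist_mean, dist_sd, bounds,
                          signal_windows) {
  stopifnot(is.character(name), length(name) == 1,
            unit %in% c("%", "mg/g", "pH-unit"),
            is.numeric(dist_mean), is.numeric(dist_sd), dist_sd >= 0,
            length(bounds) == 2, is.data.frame(signal_windows))
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy lo < hi for ", name)
  req <- c("t_lo", "t_hi", "amplitude", "width")
  if (!all(req %in% names(signal_windows)))
    stop("signal_windows needs columns ", paste(req, collapse = ", "))
  with(signal_windows, {
    if (any(t_lo >= t_hi)) stop("signal window must have t_lo < t_hi: ", name)
    if (any(!is.finite(amplitude))) stop("non-finite amplitude: ", name)
    if (any(width <= 0)) stop("window width must be positive: ", name)
  })
  structure(list(name = name, unit = unit, dist_mean = dist_mean,
                 dist_sd = dist_sd, bounds = as.numeric(bounds),
                 signal_windows = signal_windows),
            class = "component_def")
}

# helper to build a two-window component with the default amplitude scaling:
# each window contributes a peak whose across-sample standard deviation is
# `peak_sd` (in 1/degC) when contents vary by one dist_sd.
two_window_component <- function(name, unit, mean, sd, lo, hi,
                                 w1, w2, peak_sd = 1.5e-4) {
  amp <- peak_sd / sd
  windows <- data.frame(
    t_lo = c(w1[1], w2[1]), t_hi = c(w1[2], w2[2]),
    amplitude = amp,
    width = c((w1[2] - w1[1]) / 4, (w2[2] - w2[1]) / 4))
  component_def(name, unit, mean, sd, c(lo, hi), windows)
}

#' Default chemical component set
#'
#' The 19 routinely assayed tobacco components (sugars, nitrogen compounds,
#' inorganic ions, extractables and pH). Content distribution parameters are
#' illustrative values in the ranges typical for flue-cured tobacco; signal
#' windows place each component's pyrolysis response inside the two
#' decomposition stages (volatiles/monosaccharides up to ~230 degC,
#' biopolymers 230--500 degC), with a few windows at higher temperature for
#' the mineral-associated components.
#'
#' @return named list of 19 [component_def()] objects.
#' @export
default_components <- function() {
  # name, unit, mean, sd, lo, hi, window1, window2
  defs <- list(
    list("Total alkaloids",         "%",    2.5, 0.8,  0.3, 5.5,  c(160, 208), c(330, 378)),
    list("Reducing sugar",          "%",   18.0, 5.5,  4.0, 36,   c(153, 201), c(345, 397)),
    list("Total sugar",             "%",   22.0, 6.5,  5.0, 40,   c(149, 197), c(248, 300)),
    list("Total nitrogen",          "%",    2.0, 0.45, 0.8, 3.6,  c(205, 253), c(332, 384)),
    list("Potassium",               "%",    2.0, 0.6,  0.5, 4.2,  c(193, 245), c(339, 383)),
    list("Chlorine",                "%",    0.45, 0.3, 0.01, 1.8, c(135, 187), c(238, 290)),
    list("pH",                      "pH-unit", 5.4, 0.25, 4.4, 6.4, c(168, 216), c(300, 352)),
    list("Starch",                  "%",    3.5, 1.2,  0.4, 8.0,  c(175, 223), c(290, 342)),
    list("Dichloromethane extract", "%",    6.0, 1.5,  1.5, 12,   c(162, 214), c(343, 395)),
    list("Solanesol",               "mg/g", 15.0, 5.0, 2.0, 32,   c(181, 229), c(338, 390)),
    list("Sulfate",                 "mg/g", 12.0, 3.5, 2.0, 26,   c(131, 179), c(240, 292)),
    list("Phosphate",               "mg/g", 4.0, 1.0,  0.8, 8.0,  c(177, 225), c(390, 442)),
    list("Magnesium",               "%",    0.5, 0.15, 0.1, 1.1,  c(140, 192), c(478, 530)),
    list("Calcium",                 "%",    2.2, 0.7,  0.4, 5.0,  c(150, 198), c(305, 357)),
    list("Polyphenols",             "%",   25.0, 6.0,  6.0, 46,   c(129, 177), c(335, 387)),
    list("Refractory acid",         "%",   55.0, 14.0, 15,  100,  c(150, 202), c(375, 427)),
    list("Amino acids",             "%",   12.0, 4.0,  2.0, 26,   c(132, 180), c(258, 310)),
    list("Amadori compounds",       "%",   15.0, 4.5,  3.0, 30,   c(130, 178), c(250, 302)),
    list("Neophytadiene",           "mg/g", 1.5, 0.45, 0.2, 3.2,  c(231, 283), c(300, 352))
  )
  out <- lapply(defs, function(d)
    two_window_component(d[[1]], d[[2]], d[[3]], d[[4]], d[[5]], d[[6]],
                         d[[7]], d[[8]]))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

component_names <- function(components) {
  vapply(components, `[[`, character(1), "name")
}

component_units <- function(components) {
  stats::setNames(vapply(components, `[[`, character(1), "unit"),
                  component_names(components))
}
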