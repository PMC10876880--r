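#' Specification of a synthetic pyrolysis study
#'
#' Collects every parameter needed to simulate a calibration study: the
#' component set, engineered inter-component correlations, the shared
#' baseline decomposition peaks, noise magnitudes and the temperature grid.
#' The defaults emulate the scale and statistical structure of a 157-sample
#' tobacco study: two pyrolysis stages (volatile/monosaccharide loss below
#' ~230 degC, biopolymer decomposition 230--500 degC), non-uniform content
#' distributions, and a few component pairs with |r| > 0.9.
#'
#' @param n_samples number of samples to simulate (default 157).
#' @param components named list of [component_def()]s (default the 19 of
#'   [default_components()]).
#' @param corr_pairs data frame with columns `a`, `b` (component names) and
#'   `r` (target Pearson correlation of the generated contents). Targets must
#'   satisfy `|r| * (1 + assay_noise_rel^2) < 1`.
#' @param baseline_peaks data frame `center`, `width`, `amplitude` describing
#'   Gaussian mass-loss peaks (degC, degC, 1/degC) shared by every sample.
#' @param curve_noise_sd standard deviation of the per-grid-point noise on the
#'   DTG rate (1/degC). The noise is correlated along the temperature axis
#'   (see `curve_noise_corr`), as instrument noise is after differentiation
#'   and interpolation.
#' @param curve_noise_corr correlation length of the curve noise in degC
#'   (Gaussian kernel standard deviation); 0 gives white noise.
#' @param replicate_noise_sd between-replicate mass noise in mg, applied by
#'   [make_replicates()]; the default 1e-4 mg is the 0.1 microgram
#'   resolution of a research microbalance.
#' @param assay_noise_rel wet-chemistry measurement error of the composition
#'   table, as a fraction of each component's `dist_sd`. The DTG curves are
#'   rendered from the true (latent) contents; the table reports the noisy
#'   assay values, as in a real study.
#' @param grid a [grid_spec()]; default 105--900 degC in 1 degC steps (the
#'   working resolution for model fitting; preprocessing of raw traces uses
#'   its own, typically 0.1 degC, grid).
#' @param seed integer seed making all generated artifacts reproducible.
#' @return object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_samples = 10, seed = 1)
#' tab <- generate_composition(spec)
#' dim(tab)
#' @export
synthetic_spec <- function(n_samples = 157,
                           components = default_components(),
                           corr_pairs = default_corr_pairs(),
                           baseline_peaks = default_baseline_peaks(),
                           curve_noise_sd = 2e-5,
                           curve_noise_corr = 8,
                           replicate_noise_sd = 1e-4,
                           assay_noise_rel = 0.22,
                           grid = grid_spec(105, 900, 1),
                           seed = 1L) {
  stopifnot(n_samples >= 0, is.list(components), length(components) >= 1,
            inherits(grid, "grid_spec"))
  if (curve_noise_sd < 0 || replicate_noise_sd < 0 || assay_noise_rel < 0)
    stop("noise standard deviations must be non-negative")
  nms <- component_names(components)
  if (anyDuplicated(nms)) stop("duplicate component names")
  if (nrow(corr_pairs)) {
    missing <- setdiff(c(corr_pairs$a, corr_pairs$b), nms)
    if (length(missing))
      stop("corr_pairs references unknown component(s): ",
           paste(missing, collapse = ", "))
    if (any(abs(corr_pairs$r) >= 1)) stop("|target r| must be < 1")
    if (any(abs(corr_pairs$r) * (1 + assay_noise_rel^2) >= 1))
      stop("target r infeasible at assay_noise_rel = ", assay_noise_rel)
  }
  for (comp in components) {
    win <- comp$signal_windows
    if (any(win$t_lo < grid$start - 1e-9) || any(win$t_hi > grid$stop + 1e-9))
      stop("signal window of ", comp$name, " outside the temperature span")
  }
  structure(list(n_samples = as.integer(n_samples), components = components,
                 corr_pairs = corr_pairs, baseline_peaks = baseline_peaks,
                 curve_noise_sd = curve_noise_sd,
                 curve_noise_corr = curve_noise_corr,
                 replicate_noise_sd = replicate_noise_sd,
                 assay_noise_rel = assay_noise_rel,
                 grid = grid, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_corr_pairs <- function() {
  data.frame(a = c("Total sugar", "Dichloromethane extract", "Calcium"),
             b = c("Reducing sugar", "Solanesol", "Refractory acid"),
             r = c(0.95, 0.92, 0.91))
}

#' @rdname synthetic_spec
#' @export
default_baseline_peaks <- function() {
  # one volatile-stage peak, the main biopolymer peak, and a lignin shoulder
  data.frame(center = c(175, 300, 430), width = c(20, 35, 45),
             amplitude = c(0.0015, 0.003, 0.0008))
}

gaussian_peak <- function(temps, center, width, amplitude) {
  amplitude * exp(-0.5 * ((temps - center) / width)^2)
}

#' Generate a composition table
#'
#' Draws contents for each component from its truncated-normal distribution,
#' imposing the target correlations of `spec$corr_pairs` through a Gaussian
#' copula, then adds assay noise (`assay_noise_rel`). Copula correlations are
#' inflated by `1 + assay_noise_rel^2` so the *observed* table attains the
#' target Pearson r despite the attenuation caused by measurement error.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with a `sample_id` column and one column per component.
#'   The latent (noise-free) contents are attached as attribute `"latent"`
#'   and the component units as attribute `"units"`.
#' @export
generate_composition <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  comps <- spec$components
  nms <- component_names(comps)
  k <- length(comps)
  n <- spec$n_samples

  R <- diag(k)
  dimnames(R) <- list(nms, nms)
  if (nrow(spec$corr_pairs)) {
    infl <- 1 + spec$assay_noise_rel^2
    for (i in seq_len(nrow(spec$corr_pairs))) {
      a <- spec$corr_pairs$a[i]; b <- spec$corr_pairs$b[i]
      R[a, b] <- R[b, a] <- spec$corr_pairs$r[i] * infl
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    stop("corr_pairs jointly infeasible (correlation matrix not positive definite)")

  Z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
  means <- vapply(comps, `[[`, numeric(1), "dist_mean")
  sds <- vapply(comps, `[[`, numeric(1), "dist_sd")
  latent <- sweep(sweep(Z, 2, sds, `*`), 2, means, `+`)
  observed <- latent +
    matrix(stats::rnorm(n * k), n, k) %*% diag(spec$assay_noise_rel * sds, k)
  for (j in seq_len(k)) {
    b <- comps[[j]]$bounds
    latent[, j] <- pmin(pmax(latent[, j], b[1]), b[2])
    observed[, j] <- pmin(pmax(observed[, j], b[1]), b[2])
  }
  colnames(latent) <- colnames(observed) <- nms
  tab <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    observed, check.names = FALSE)
  attr(tab, "latent") <- latent
  attr(tab, "units") <- component_units(comps)
  tab
}

# temperature-correlated Gaussian noise, one row per sample; sd is the
# marginal per-point standard deviation regardless of the correlation length
correlated_noise <- function(n, temps, sd, corr_len) {
  p <- length(temps)
  E <- matrix(stats::rnorm(n * p), n, p)
  if (sd == 0) return(matrix(0, n, p))
  if (corr_len <= 0) return(E * sd)
  step <- if (p > 1) temps[2] - temps[1] else 1
  half <- max(1L, ceiling(4 * corr_len / step))
  kern <- stats::dnorm(seq(-half, half) * step, sd = corr_len)
  kern <- kern / sqrt(sum(kern^2))  # unit l2 norm preserves the marginal sd
  pad <- function(e) c(rev(e[seq_len(half)]), e, rev(e[seq(p - half + 1, p)]))
  sm <- t(apply(E, 1, function(e)
    stats::filter(pad(e), kern, sides = 2)[(half + 1):(half + p)]))
  sm * sd
}

# p x k matrix of per-unit-content DTG responses for the component set
component_profiles <- function(components, temps) {
  k <- length(components)
  prof <- matrix(0, length(temps), k)
  for (j in seq_len(k)) {
    win <- components[[j]]$signal_windows
    for (w in seq_len(nrow(win))) {
      center <- (win$t_lo[w] + win$t_hi[w]) / 2
      prof[, j] <- prof[, j] +
        gaussian_peak(temps, center, win$width[w], win$amplitude[w])
    }
  }
  colnames(prof) <- component_names(components)
  prof
}

baseline_curve <- function(baseline_peaks, temps) {
  out <- numeric(length(temps))
  for (i in seq_len(nrow(baseline_peaks)))
    out <- out + gaussian_peak(temps, baseline_peaks$center[i],
                               baseline_peaks$width[i],
                               baseline_peaks$amplitude[i])
  out
}

#' Generate DTG curves for a composition table
#'
#' Each sample's mass-loss rate is the shared baseline plus, for every
#' component, its content times the component's signal-window peaks, plus
#' temperature-correlated noise. With `curve_noise_sd = 0` the map from
#' contents to curves is exactly linear. If the table carries a `"latent"`
#' attribute (as produced by [generate_composition()]), curves are rendered
#' from those noise-free contents, so that assay error stays on the response
#' side of any later calibration.
#'
#' @param table composition table whose component columns match
#'   `spec$components`.
#' @param spec a [synthetic_spec()].
#' @return list of `dtg_curve` objects (one per sample).
#' @export
generate_dtg_curves <- function(table, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nms <- component_names(spec$components)
  if (!all(nms %in% names(table)))
    stop("composition table is missing component column(s): ",
         paste(setdiff(nms, names(table)), collapse = ", "))
  contents <- attr(table, "latent")
  if (is.null(contents)) contents <- as.matrix(table[, nms, drop = FALSE])
  contents <- contents[, nms, drop = FALSE]
  n <- nrow(contents)
  temps <- grid_temperatures(spec$grid)
  prof <- component_profiles(spec$components, temps)
  base <- baseline_curve(spec$baseline_peaks, temps)

  set.seed(spec$seed + 1L)
  noise <- correlated_noise(n, temps, spec$curve_noise_sd, spec$curve_noise_corr)
  rates <- tcrossprod(contents, prof) +
    matrix(base, n, length(temps), byrow = TRUE) + noise

  ids <- if ("sample_id" %in% names(table)) table$sample_id
         else sprintf("S%03d", seq_len(n))
  lapply(seq_len(n), function(i)
    dtg_curve(ids[i], spec$grid, rates[i, ]))
}

#' Construct a DTG curve object
#'
#' @param sample_id sample identifier.
#' @param grid a [grid_spec()].
#' @param rate mass-loss rate (fraction of reference mass per degC) at each
#'   grid point; length must equal `grid$count`.
#' @return object of class `dtg_curve`.
#' @export
dtg_curve <- function(sample_id, grid, rate) {
  stopifnot(inherits(grid, "grid_spec"))
  rate <- as.numeric(rate)
  if (length(rate) != grid$count)
    stop("rate length ", length(rate), " != grid count ", grid$count)
  if (any(!is.finite(rate))) stop("non-finite DTG rate")
  structure(list(sample_id = sample_id, grid = grid, rate = rate),
            class = "dtg_curve")
}

#' @export
print.dtg_curve <- function(x, ...) {
  cat(sprintf("<dtg_curve> %s: %d points on %g-%g degC, peak rate %.3g/degC\n",
              x$sample_id, x$grid$count, x$grid$start, x$grid$stop,
              max(x$rate)))
  invisible(x)
}

#' Assemble DTG curves into a sample x temperature matrix
#'
#' @param curves list of `dtg_curve` objects sharing one grid.
#' @return numeric matrix (samples in rows) with sample ids as row names,
#'   temperatures as column names and a numeric `"temperature"` attribute.
#' @export
dtg_matrix <- function(curves) {
  stopifnot(length(curves) >= 1)
  g <- curves[[1]]$grid
  for (cv in curves) if (!same_grid(cv$grid, g)) stop("curves on different grids")
  X <- do.call(rbind, lapply(curves, `[[`, "rate"))
  rownames(X) <- vapply(curves, function(cv) as.character(cv$sample_id), "")
  temps <- grid_temperatures(g)
  colnames(X) <- formatC(temps, format = "fg")
  attr(X, "temperature") <- temps
  X
}

#' Render a synthetic raw TGA trace from a DTG curve
#'
#' Simulates the instrument record of the standard protocol: a 105 degC
#' drying hold followed by a constant-rate ramp, sampled uniformly in time.
#' The mass trajectory is the integral of the DTG rate along the ramp, scaled
#' by the initial mass. At 120 samples/min and 10 degC/min the ramp
#' temperature step is 1/12 degC, so preprocessing back onto a 0.1 degC grid
#' recovers the input curve to interpolation accuracy.
#'
#' @param curve a [dtg_curve()].
#' @param initial_mass_mg sample mass in mg at the end of the drying hold
#'   (default 10.0, the nominal weighed-in mass).
#' @param spec optional [synthetic_spec()] (unused fields reserved).
#' @param hold_min duration of the 105 degC hold in minutes.
#' @param points_per_min instrument sampling rate (default 120).
#' @param ramp_rate heating rate in degC/min (default 10).
#' @return object of class `tga_trace`: a data frame with columns `time_min`,
#'   `temperature_C`, `mass_mg`, plus attributes `sample_id` and `segment`
#'   (`"hold"`/`"ramp"`).
#' @export
render_tga_trace <- function(curve, initial_mass_mg = 10.0, spec = NULL,
                             hold_min = 30, points_per_min = 120,
                             ramp_rate = 10) {
  stopifnot(inherits(curve, "dtg_curve"))
  if (!is.numeric(initial_mass_mg) || initial_mass_mg <= 0)
    stop("initial_mass_mg must be positive")
  g <- curve$grid
  dt <- 1 / points_per_min
  t_hold <- seq(0, hold_min, by = dt)
  ramp_span <- (g$stop + 2 * g$step) - g$start
  t_ramp <- seq(dt, ramp_span / ramp_rate, by = dt) + hold_min
  temps_ramp <- g$start + ramp_rate * (t_ramp - hold_min)

  rate_ramp <- stats::approx(grid_temperatures(g), curve$rate,
                             xout = pmin(temps_ramp, g$stop), rule = 2)$y
  dT <- diff(c(g$start, temps_ramp))
  # trapezoidal integral of the rate from the hold end up to each ramp sample
  mid <- (rate_ramp + c(curve$rate[1], rate_ramp[-length(rate_ramp)])) / 2
  lost <- cumsum(mid * dT)
  mass_ramp <- initial_mass_mg * (1 - lost)

  out <- data.frame(
    time_min = c(t_hold, t_ramp),
    temperature_C = c(rep(g$start, length(t_hold)), temps_ramp),
    mass_mg = c(rep(initial_mass_mg, length(t_hold)), mass_ramp))
  structure(out, sample_id = curve$sample_id,
            segment = c(rep("hold", length(t_hold)),
                        rep("ramp", length(t_ramp))),
            class = c("tga_trace", "data.frame"))
}

#' Simulate replicate TGA runs
#'
#' Adds independent mass noise (`spec$replicate_noise_sd`, in mg) to a trace
#' to emulate repeated experiments on the same sample; with zero noise all
#' replicates are identical to the input.
#'
#' @param trace a `tga_trace`.
#' @param n_reps number of replicates (>= 1).
#' @param spec a [synthetic_spec()] providing `replicate_noise_sd` and `seed`.
#' @return list of `n_reps` traces.
#' @export
make_replicates <- function(trace, n_reps, spec) {
  stopifnot(inherits(trace, "tga_trace"), n_reps >= 1,
            inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  lapply(seq_len(n_reps), function(i) {
    rep <- trace
    rep$mass_mg <- trace$mass_mg +
      stats::rnorm(nrow(trace), 0, spec$replicate_noise_sd)
    attr(rep, "replicate") <- i
    rep
  })
}
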