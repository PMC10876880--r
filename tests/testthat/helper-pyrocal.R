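# Shared fixtures, all built in code.

# three well-separated components on a compact grid, for fast tests
tiny_components <- function() {
  win <- function(lo, hi, amp) {
    data.frame(t_lo = lo, t_hi = hi, amplitude = amp, width = (hi - lo) / 4)
  }
  list(
    A = component_def("A", "%", 10, 3, c(0, 25),
                      rbind(win(150, 200, 5e-5), win(330, 380, 5e-5))),
    B = component_def("B", "%", 5, 1.5, c(0, 12), win(230, 280, 1e-4)),
    C = component_def("C", "mg/g", 2, 0.5, c(0, 5), win(400, 450, 3e-4))
  )
}

no_pairs <- function() data.frame(a = character(0), b = character(0),
                                  r = numeric(0))

tiny_spec <- function(n_samples = 20, seed = 1, ...) {
  synthetic_spec(n_samples = n_samples, components = tiny_components(),
                 corr_pairs = no_pairs(), grid = grid_spec(105, 550, 1),
                 seed = seed, ...)
}

# study conditions for the interval-recovery experiment: one target
# component with known signal windows at 200-260 and 330-380 degC
recovery_spec <- function(seed, n_samples = 157) {
  target <- default_components()[["Total nitrogen"]]
  target$signal_windows$t_lo <- c(200, 330)
  target$signal_windows$t_hi <- c(260, 380)
  target$signal_windows$width <- c(15, 12.5)
  synthetic_spec(n_samples = n_samples,
                 components = list("Total nitrogen" = target),
                 corr_pairs = no_pairs(), seed = seed)
}

recovery_truth <- function() interval_set(c(200, 330), c(260, 380))

# hand-built trace helpers
flat_trace <- function(mass = 5, temps = seq(100, 200, by = 10)) {
  structure(data.frame(time_min = seq_along(temps),
                       temperature_C = temps,
                       mass_mg = rep(mass, length(temps))),
            sample_id = "flat", class = c("tga_trace", "data.frame"))
}

normalized_trace <- function(temps, mass) {
  structure(data.frame(time_min = seq_along(temps),
                       temperature_C = temps, mass_mg = mass),
            sample_id = "manual", normalized = TRUE,
            class = c("tga_trace", "data.frame"))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
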