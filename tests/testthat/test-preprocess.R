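test_that("grid arithmetic honours the stated range and step", {
  g <- grid_spec()
  expect_equal(g$count, 7951L)
  expect_equal(grid_temperatures(grid_spec(105, 110, 1)), 105:110)
  expect_equal(grid_spec(105, 900, 1)$count, 796L)
  expect_error(grid_spec(step = 0), "positive")
  expect_error(grid_spec(900, 105), "exceed")
})

test_that("normalization divides by the hold-end mass and is scale invariant", {
  tr <- flat_trace(mass = 5)
  nt <- normalize_trace(tr, t_start = 105)
  expect_true(all(nt$mass_mg == 1))
  expect_equal(attr(nt, "reference_mass_mg"), 5)
  expect_true(all(nt$temperature_C >= 105))

  ramp <- structure(data.frame(time_min = 1:6,
                               temperature_C = c(100, 105, 120, 140, 160, 180),
                               mass_mg = c(8, 8, 7, 6, 5, 4)),
                    class = c("tga_trace", "data.frame"))
  a <- normalize_trace(ramp)
  scaled <- ramp
  scaled$mass_mg <- ramp$mass_mg * 3.7
  b <- normalize_trace(scaled)
  expect_equal(a$mass_mg, b$mass_mg)

  bad <- ramp
  bad$mass_mg[2] <- -1
  expect_error(normalize_trace(bad), "positive")
  expect_error(normalize_trace(ramp, t_start = 50), "no point")
})

test_that("central differencing is exact on lines and quadratics", {
  temps <- seq(110, 200, by = 5)
  lin <- normalized_trace(temps, 1 - 0.001 * temps)
  d <- differentiate(lin)
  expect_equal(d$rate, rep(0.001, length(temps)), tolerance = 1e-12)

  const <- normalized_trace(temps, rep(0.8, length(temps)))
  expect_equal(differentiate(const)$rate, rep(0, length(temps)))

  quad <- normalized_trace(temps, 1 - 1e-5 * temps^2)
  dq <- differentiate(quad)
  interior <- 2:(length(temps) - 1)
  expect_equal(dq$rate[interior], 2e-5 * temps[interior], tolerance = 1e-10)

  # duplicate temperatures (isothermal hold) collapse by averaging
  hold <- normalized_trace(c(105, 105, 105, 110, 115),
                           c(1.02, 1.00, 0.98, 0.95, 0.90))
  dh <- differentiate(hold)
  expect_equal(dh$temperature_C, c(105, 110, 115))
  expect_equal(dh$rate[1], -(0.95 - 1.00) / 5)

  unnorm <- flat_trace()
  expect_error(differentiate(unnorm), "normalize")
})

test_that("grid interpolation is the identity on grid points and exact on lines", {
  g <- grid_spec(105, 110, 0.5)
  temps <- grid_temperatures(g)
  raw <- data.frame(temperature_C = temps, rate = sin(temps))
  out <- interpolate_to_grid(raw, g)
  expect_s3_class(out, "dtg_curve")
  expect_length(out$rate, g$count)
  expect_equal(out$rate, sin(temps))

  coarse <- data.frame(temperature_C = c(104, 107, 112),
                       rate = 2 * c(104, 107, 112) + 1)
  expect_equal(interpolate_to_grid(coarse, g)$rate, 2 * temps + 1)

  short <- data.frame(temperature_C = c(106, 112), rate = c(0, 0))
  expect_error(interpolate_to_grid(short, g), "lower")
  short2 <- data.frame(temperature_C = c(104, 108), rate = c(0, 0))
  expect_error(interpolate_to_grid(short2, g), "upper")
})

test_that("NRMSE matches its closed form and normalizes by the reference range", {
  g <- grid_spec(105, 205, 1)
  temps <- grid_temperatures(g)
  rate <- exp(-0.5 * ((temps - 150) / 10)^2)  # range 1 (max 1, min ~0)
  a <- dtg_curve("a", g, rate)
  expect_equal(compute_nrmse(a, a), 0)

  shifted <- dtg_curve("b", g, rate + 0.03)
  rng <- max(rate) - min(rate)
  expect_equal(compute_nrmse(a, shifted), 100 * 0.03 / rng, tolerance = 1e-10)

  sa <- dtg_curve("a", g, rate * 4)
  sb <- dtg_curve("b", g, (rate + 0.03) * 4)
  expect_equal(compute_nrmse(sa, sb), compute_nrmse(a, shifted))

  flat <- dtg_curve("c", g, rep(0.5, g$count))
  expect_error(compute_nrmse(flat, a), "range")
})

test_that("render + preprocess round-trips a synthetic curve and conserves mass", {
  spec <- tiny_spec(n_samples = 2, seed = 3, curve_noise_sd = 0)
  tab <- generate_composition(spec)
  curve <- generate_dtg_curves(tab, spec)[[1]]
  trace <- render_tga_trace(curve, initial_mass_mg = 10, spec)

  # protocol arithmetic: 10 degC/min at 120 points/min = 1/12 degC per sample
  ramp <- attr(trace, "segment") == "ramp"
  steps <- diff(trace$temperature_C[ramp])
  expect_equal(unique(round(steps, 9)), round(1 / 12, 9))

  rec <- preprocess_trace(trace, spec$grid)
  err <- max(abs(rec$rate - curve$rate))
  expect_lt(err, 1e-3 * max(curve$rate))

  # normalized mass at the hold end is exactly 1
  nt <- normalize_trace(trace)
  expect_equal(nt$mass_mg[1], 1.0)

  # integral of the DTG curve ~ total normalized mass lost over the grid
  temps <- grid_temperatures(spec$grid)
  lost <- 1 - min(nt$mass_mg)
  expect_equal(trapz(temps, rec$rate), lost, tolerance = 1e-3)

  # zero-rate curve renders a constant-mass trace
  zero <- dtg_curve("z", spec$grid, rep(0, spec$grid$count))
  zt <- render_tga_trace(zero, 10, spec)
  expect_equal(unique(zt$mass_mg), 10)
  expect_error(render_tga_trace(curve, initial_mass_mg = 0), "positive")
})

test_that("round-trip holds on the fine default 0.1 degC grid", {
  g <- grid_spec(105, 300, 0.1)
  temps <- grid_temperatures(g)
  rate <- 2e-4 * exp(-0.5 * ((temps - 180) / 15)^2) +
    1e-4 * exp(-0.5 * ((temps - 250) / 10)^2)
  curve <- dtg_curve("fine", g, rate)
  trace <- render_tga_trace(curve, 10)
  rec <- preprocess_trace(trace, g)
  expect_lt(max(abs(rec$rate - curve$rate)), 1e-3 * max(curve$rate))
})
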