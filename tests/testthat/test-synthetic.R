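test_that("composition generation respects bounds, seeds and degenerate cases", {
  spec <- synthetic_spec(n_samples = 0, seed = 1)
  empty <- generate_composition(spec)
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 20)  # sample_id + 19 components
  expect_setequal(setdiff(names(empty), "sample_id"),
                  names(default_components()))

  spec <- synthetic_spec(n_samples = 50, seed = 7)
  tab1 <- generate_composition(spec)
  tab2 <- generate_composition(spec)
  expect_identical(tab1, tab2)  # bit-identical for fixed spec + seed

  for (comp in spec$components) {
    v <- tab1[[comp$name]]
    expect_true(all(v >= comp$bounds[1] & v <= comp$bounds[2]))
  }

  # dist_sd -> 0 collapses every column (and its assay noise) to the mean
  comps <- tiny_components()
  for (nm in names(comps)) comps[[nm]]$dist_sd <- 0
  dspec <- synthetic_spec(n_samples = 8, components = comps,
                          corr_pairs = no_pairs(),
                          grid = grid_spec(105, 550, 1), seed = 2)
  dtab <- generate_composition(dspec)
  expect_equal(dtab$A, rep(10, 8))
  expect_equal(dtab$B, rep(5, 8))

  bad <- data.frame(a = "A", b = "Nope", r = 0.5)
  expect_error(synthetic_spec(components = tiny_components(),
                              corr_pairs = bad), "Nope")
})

test_that("engineered pair correlations hit their targets at large n", {
  spec <- synthetic_spec(n_samples = 1000, seed = 21)
  tab <- generate_composition(spec)
  cm <- correlation_matrix(tab)
  for (i in seq_len(nrow(spec$corr_pairs))) {
    got <- cm[spec$corr_pairs$a[i], spec$corr_pairs$b[i]]
    expect_lt(abs(got - spec$corr_pairs$r[i]), 0.05)
  }
})

test_that("the content-to-curve map is linear with additive baseline", {
  spec <- tiny_spec(n_samples = 3, curve_noise_sd = 0)
  temps <- grid_temperatures(spec$grid)

  zero_tab <- data.frame(sample_id = c("z1", "z2"), A = 0, B = 0, C = 0)
  zc <- generate_dtg_curves(zero_tab, spec)
  expect_equal(zc[[1]]$rate, zc[[2]]$rate)
  baseline <- zc[[1]]$rate
  expect_true(all(baseline >= 0))

  tab <- data.frame(sample_id = c("s1", "s2"), A = c(2, 4), B = 0, C = 0)
  cs <- generate_dtg_curves(tab, spec)
  d1 <- cs[[1]]$rate - baseline
  d2 <- cs[[2]]$rate - baseline
  expect_equal(d2, 2 * d1, tolerance = 1e-12)  # doubling doubles the imprint

  # superposition: curve(A + B) = baseline + imprint(A) + imprint(B)
  tA <- data.frame(sample_id = "a", A = 3, B = 0, C = 0)
  tB <- data.frame(sample_id = "b", A = 0, B = 2, C = 0)
  tAB <- data.frame(sample_id = "ab", A = 3, B = 2, C = 0)
  iA <- generate_dtg_curves(tA, spec)[[1]]$rate - baseline
  iB <- generate_dtg_curves(tB, spec)[[1]]$rate - baseline
  iAB <- generate_dtg_curves(tAB, spec)[[1]]$rate - baseline
  expect_equal(iAB, iA + iB, tolerance = 1e-12)
})

test_that("default curves lose mass in both pyrolysis stages", {
  spec <- synthetic_spec(n_samples = 3, seed = 5)
  tab <- generate_composition(spec)
  curves <- generate_dtg_curves(tab, spec)
  temps <- grid_temperatures(spec$grid)
  for (cv in curves) {
    s1 <- temps >= 105 & temps <= 230
    s2 <- temps >= 230 & temps <= 500
    expect_gt(trapz(temps[s1], cv$rate[s1]), 0)
    expect_gt(trapz(temps[s2], cv$rate[s2]), 0)
  }
  # identical spec + seed: bit-identical curves
  again <- generate_dtg_curves(tab, spec)
  expect_identical(lapply(curves, `[[`, "rate"), lapply(again, `[[`, "rate"))
})

test_that("replicates are identical at zero noise and diverge with it", {
  spec <- tiny_spec(n_samples = 1, seed = 9, curve_noise_sd = 0,
                    replicate_noise_sd = 0)
  tab <- generate_composition(spec)
  curve <- generate_dtg_curves(tab, spec)[[1]]
  trace <- render_tga_trace(curve, 10, spec)

  reps <- make_replicates(trace, 3, spec)
  expect_length(reps, 3)
  expect_equal(reps[[1]]$mass_mg, trace$mass_mg)
  expect_equal(reps[[2]]$mass_mg, reps[[3]]$mass_mg)
  c1 <- preprocess_trace(reps[[1]], spec$grid)
  c2 <- preprocess_trace(reps[[2]], spec$grid)
  expect_equal(compute_nrmse(c1, c2), 0)

  one <- make_replicates(trace, 1, spec)
  expect_length(one, 1)

  # mean pairwise NRMSE grows with the replicate noise (over 20 seeds)
  mean_nrmse <- function(sd) {
    vals <- vapply(1:20, function(s) {
      sp <- tiny_spec(n_samples = 1, seed = 100 + s, curve_noise_sd = 0,
                      replicate_noise_sd = sd)
      rp <- make_replicates(trace, 2, sp)
      compute_nrmse(preprocess_trace(rp[[1]], sp$grid),
                    preprocess_trace(rp[[2]], sp$grid))
    }, numeric(1))
    mean(vals)
  }
  low <- mean_nrmse(0.002)
  high <- mean_nrmse(0.02)
  expect_gt(high, low)
})
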