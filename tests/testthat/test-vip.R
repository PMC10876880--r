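test_that("VIP normalization is forced for p = 1 and the mean-square identity holds", {
  set.seed(1)
  X <- matrix(rnorm(20), 20, 1)
  y <- 2 * X[, 1] + rnorm(20, 0, 0.1)
  m <- fit_pls(X, y, 1)
  v <- vip_scores(m, 105)
  expect_equal(v$vip, 1)

  for (i in 1:10) {
    n <- sample(15:40, 1); p <- sample(4:50, 1)
    Xr <- matrix(rnorm(n * p), n)
    yr <- drop(Xr %*% rnorm(p)) + rnorm(n)
    mr <- fit_pls(Xr, yr, sample(1:4, 1))
    vr <- vip_scores(mr, seq_len(p))
    expect_equal(mean(vr$vip^2), 1, tolerance = 1e-10)
  }
})

test_that("one latent variable concentrates VIP on the informative predictor", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(30 * 6), 30)))
  y <- 5 * Q[, 4]
  m <- fit_pls(Q, y, 1, center = FALSE)
  v <- vip_scores(m, seq_len(6))
  expect_equal(v$vip[4], sqrt(6), tolerance = 1e-8)
  expect_lt(max(v$vip[-4]), 1e-6)
})

test_that("interval extraction thresholds, merges and filters runs", {
  prof <- structure(list(temperature = seq(105.0, 105.4, by = 0.1),
                         vip = c(0.5, 1.2, 1.3, 0.8, 1.1), ncomp = 1L),
                    class = "vip_profile")
  iv <- extract_intervals(prof, threshold = 1, min_run = 0, merge_gap = 0)
  expect_equal(iv$t_lo, c(105.1, 105.4))
  expect_equal(iv$t_hi, c(105.2, 105.4))

  low <- structure(list(temperature = 1:10, vip = rep(0.4, 10), ncomp = 1L),
                   class = "vip_profile")
  expect_equal(nrow(extract_intervals(low)), 0)

  # gaps narrower than merge_gap are bridged; short runs are dropped
  temps <- seq(100, 160, by = 1)
  vip <- rep(0.5, length(temps))
  vip[temps >= 110 & temps <= 120] <- 1.5
  vip[temps >= 123 & temps <= 135] <- 1.5   # 3 degC gap
  vip[temps == 150] <- 1.5                  # isolated point
  prof2 <- structure(list(temperature = temps, vip = vip, ncomp = 1L),
                     class = "vip_profile")
  got <- extract_intervals(prof2, threshold = 1, min_run = 2, merge_gap = 5)
  expect_equal(got$t_lo, 110)
  expect_equal(got$t_hi, 135)
  apart <- extract_intervals(prof2, threshold = 1, min_run = 0, merge_gap = 1)
  expect_equal(nrow(apart), 3)
})

test_that("raising the threshold never enlarges the selected union", {
  set.seed(3)
  temps <- seq(105, 300, by = 1)
  vip <- abs(stats::filter(rnorm(length(temps)), rep(1, 7) / 7,
                           circular = TRUE)) * 2
  prof <- structure(list(temperature = temps, vip = as.numeric(vip),
                         ncomp = 1L), class = "vip_profile")
  len <- function(iv) if (nrow(iv)) sum(iv$t_hi - iv$t_lo) else 0
  last <- Inf
  for (th in c(0.5, 0.8, 1, 1.3, 1.7)) {
    l <- len(extract_intervals(prof, threshold = th, min_run = 0,
                               merge_gap = 0))
    expect_lte(l, last)
    last <- l
  }
})

test_that("interval sets format compactly and report overlap correctly", {
  temps <- seq(105, 900, by = 1)
  vip <- rep(0.5, length(temps))
  vip[(temps >= 150 & temps <= 390) | (temps >= 510 & temps <= 520) |
        (temps >= 688 & temps <= 701)] <- 1.4
  prof <- structure(list(temperature = temps, vip = vip, ncomp = 1L),
                    class = "vip_profile")
  iv <- extract_intervals(prof)
  expect_equal(format_intervals(iv), "150-390,510-520,688-701")

  a <- interval_set(c(100, 300), c(200, 400))
  expect_equal(interval_jaccard(a, a), 1)
  b <- interval_set(500, 600)
  expect_equal(interval_jaccard(a, b), 0)
  c2 <- interval_set(150, 250)  # overlaps [100,200] by 50; union length 250
  expect_equal(interval_jaccard(interval_set(100, 200), c2), 50 / 150)
  expect_error(interval_set(c(100, 150), c(160, 200)), "disjoint")
})

test_that("interval restriction selects the right columns", {
  g <- grid_spec(105, 106, 0.1)
  X <- matrix(rnorm(3 * g$count), 3)
  attr(X, "temperature") <- grid_temperatures(g)

  full <- restrict_to_intervals(X, interval_set(105, 106))
  expect_equal(dim(full), dim(X))
  expect_equal(unname(full), unname(X))

  three <- restrict_to_intervals(X, interval_set(105.0, 105.2))
  expect_equal(ncol(three), 3)

  twoiv <- restrict_to_intervals(X, interval_set(c(105.0, 105.5),
                                                 c(105.2, 105.6)))
  expect_equal(ncol(twoiv), 3 + 2)
  expect_error(restrict_to_intervals(X, interval_set(numeric(0), numeric(0))),
               "empty")
})

test_that("refit on the full grid changes nothing and excluding the signal collapses fit", {
  spec <- recovery_spec(seed = 31, n_samples = 60)
  tab <- generate_composition(spec)
  X <- dtg_matrix(generate_dtg_curves(tab, spec))
  y <- tab[["Total nitrogen"]]
  split <- split_dataset(nrow(X), 0.25, seed = 1)

  g <- spec$grid
  rc <- refit_and_compare(X, y, interval_set(g$start, g$stop), split,
                          max_A = 10, cv_folds = 5, seed = 1)
  expect_equal(rc$delta$r2_train, 0)
  expect_equal(rc$delta$r2_test, 0)

  # negative control: intervals far from the 200-260 / 330-380 signal
  away <- refit_and_compare(X, y, interval_set(600, 750), split,
                            max_A = 10, cv_folds = 5, seed = 1)
  restricted <- away$comparison[away$comparison$fit == "restricted", ]
  expect_lt(restricted$r2_test, 0.3)
})

test_that("full-mixture VIP intervals cover the target's true windows", {
  # with 19 overlapping components the VIP>1 region is broader than the
  # target's own windows (interference contributes real importance), but it
  # must still contain them
  spec <- synthetic_spec(seed = 17)
  tab <- generate_composition(spec)
  X <- dtg_matrix(generate_dtg_curves(tab, spec))
  y <- tab[["Total nitrogen"]]
  A <- select_n_latent(X, y, max_A = 15, cv_folds = 5, seed = 1)
  m <- fit_pls(X, y, A)
  iv <- extract_intervals(vip_scores(m, attr(X, "temperature")))
  truth <- interval_set(c(205, 332), c(253, 384))  # default windows
  inter <- interval_jaccard(iv, truth)
  expect_gt(inter, 0)
  # coverage: nearly all of the truth length lies inside the selection
  len_truth <- sum(truth$t_hi - truth$t_lo)
  cov <- 0
  for (i in seq_len(nrow(iv))) for (j in seq_len(nrow(truth))) {
    lo <- max(iv$t_lo[i], truth$t_lo[j]); hi <- min(iv$t_hi[i], truth$t_hi[j])
    if (hi > lo) cov <- cov + (hi - lo)
  }
  expect_gt(cov / len_truth, 0.9)
})
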