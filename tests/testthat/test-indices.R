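test_that("the CSR crossover radius matches the continuum oracle for a planted core", {
  # fully occupied disk of radius 75 in a domain of radius 150:
  # F_r = 4 inside the disk, 0 outside, so the unity crossing sits at 75
  L <- 50
  delta <- 150 / L
  mids <- delta * seq_len(L) - delta / 2
  sig <- make_signal("radial", ifelse(mids < 75, 4, 0))
  r <- find_r_csr(sig)
  expect_lt(abs(r - 75), delta)
})

test_that("degenerate radial signals give the limiting crossover radii", {
  always_above <- make_signal("radial", rep(1.01, 20))
  expect_equal(find_r_csr(always_above), 150)
  expect_equal(radial_index(find_r_csr(always_above), 150), 0)

  never_above <- make_signal("radial", rep(0.8, 20))
  expect_equal(find_r_csr(never_above), 0)
  expect_equal(radial_index(0, 150), 1)

  expect_error(find_r_csr(make_signal("radial", 2)), "too short")
})

test_that("the crossover ignores dips shorter than the persistence window", {
  v <- c(2, 2, 2, 0.5, 2, 2, 2, 2, 0.5, 0.4, 0.3, 0.2)
  sig <- make_signal("radial", v, R = 120)  # 12 bins of width 10
  # single-bin dip at bin 4 is skipped; the persistent crossing is at bins 8->9
  r <- find_r_csr(sig, persistence = 3)
  expect_gt(r, 75)  # between the midpoints of bins 8 and 9
  expect_lt(r, 85)
  # with persistence 1 the same signal still picks the *last* crossing
  expect_equal(find_r_csr(sig, persistence = 1), r)
})

test_that("scalar indices are the stated arithmetic transforms", {
  expect_equal(radial_index(570.4, 817.3), 1 - 570.4 / 817.3)  # about 0.302
  expect_equal(round(radial_index(570.4, 817.3), 3), 0.302)
  expect_error(radial_index(900, 817.3), "inconsistent radii")

  sig <- make_signal("pair_angle", c(3.5, rep(0.5, 9)))
  expect_equal(pair_correlation_index(sig), 2.5)

  g <- four_cluster_pattern(21, 150)
  expect_equal(round(area_fraction_index(density_summary(g)), 3), 0.975)
  empty <- grid_from_matrix(matrix(0L, 9, 9), centre = c(5, 5))
  expect_equal(area_fraction_index(density_summary(empty)), 1)
  expect_warning(ia <- area_fraction_index(list(rho = 1.02)), "clamping")
  expect_equal(ia, 0)
})

test_that("a CSR disk has near-zero aggregation index", {
  g <- random_disk(0.1, R = 80, seed = 17)
  pc <- pair_correlation_metric(g, 50, n_s = 400, seed = 2)
  expect_lt(abs(pair_correlation_index(pc)), 0.3)
})

test_that("colony analysis separates uniform from filamentous morphologies", {
  base_spec <- filament_spec(R = 120, core_radius = 60, filament_density = 0,
                             background_density = 0, core_taper = 3, seed = 23)
  uniform <- analyze_colony(filamentous_colony(base_spec), L = 30, seed = 1)
  expect_lt(uniform$I_r, 0.15)
  expect_lt(uniform$I_theta, 0.5)
  expect_lt(abs(uniform$I_Theta), 1)

  fil_spec <- filament_spec(R = 120, core_radius = 60, filament_length = 55,
                            filament_halfwidth = 0.012, filament_density = 0.9,
                            background_density = 0.005, core_taper = 3, seed = 23)
  fil <- analyze_colony(filamentous_colony(fil_spec), L = 30, seed = 1)
  expect_gt(fil$I_r, uniform$I_r)
  expect_gt(fil$I_theta, uniform$I_theta)
  expect_gt(fil$I_Theta, uniform$I_Theta)
  expect_gt(fil$I_a, uniform$I_a)

  expect_error(analyze_colony(grid_from_matrix(matrix(0L, 5, 5), centre = c(3, 3))),
               "empty colony")
})

test_that("colony analysis is deterministic given the subsampling seed", {
  g <- filamentous_colony(filament_spec(R = 100, core_radius = 45,
                                        filament_density = 0.9, seed = 29))
  r1 <- analyze_colony(g, L = 25, n_s = 200, seed = 11)
  r2 <- analyze_colony(g, L = 25, n_s = 200, seed = 11)
  expect_identical(r1, r2)
})

test_that("angular peaks recover planted filament directions", {
  angles <- c(-2.5, -0.9, 0.4, 2.1)
  g <- filamentous_colony(filament_spec(
    R = 150, core_radius = 75, filament_angles = angles, filament_length = 60,
    filament_halfwidth = 0.008, filament_density = 0.9,
    background_density = 0.005, seed = 31))
  rcsr <- find_r_csr(radial_metric(g, 50))
  ang <- angular_metric(extract_annulus(g, rcsr), 200)
  pk <- find_angular_peaks(ang, 4)
  binw <- 2 * pi / 200
  for (a in angles) {
    expect_true(any(colonymetrics:::circular_distance(pk$theta, a) <= binw))
  }
})

test_that("sample summaries compute means, SEM and trend fits", {
  rec1 <- tibble::tibble(colony = 1, t = c(0, 10), I_r = c(0.2, 0.2),
                         I_theta = 0.1, I_Theta = 0.05, I_a = 0.5)
  rec2 <- tibble::tibble(colony = 2, t = c(0, 10), I_r = c(0.4, 0.4),
                         I_theta = 0.1, I_Theta = 0.05, I_a = 0.5)
  s <- summarize_sample(dplyr::bind_rows(rec1, rec2), fit_degree = NA)
  td <- tidy(s)
  ir <- td[td$index == "I_r", ]
  expect_equal(ir$mean, c(0.3, 0.3))
  expect_equal(ir$sem, rep(sd(c(0.2, 0.4)) / sqrt(2), 2))
  expect_equal(ir$sem, rep(0.1, 2))
  # identical colonies give SEM 0
  rec2b <- dplyr::mutate(rec1, colony = 2)
  s0 <- summarize_sample(dplyr::bind_rows(rec1, rec2b), fit_degree = NA)
  expect_true(all(tidy(s0)$sem == 0))

  # mismatched time grids are rejected
  bad <- dplyr::bind_rows(rec1, dplyr::mutate(rec2, t = c(0, 99))[2, ])
  expect_error(summarize_sample(bad), "inconsistent time points")

  # a sextic fit through 8 time points reproduces a sextic trajectory
  tt <- seq(0, 233, length.out = 8)
  poly_vals <- 0.1 + 1e-12 * tt^6 + 1e-6 * tt^2
  set.seed(1)
  recs <- dplyr::bind_rows(
    tibble::tibble(colony = 1, t = tt, I_r = poly_vals, I_theta = 0.1,
                   I_Theta = stats::rnorm(8, 0, 0.01), I_a = 0.5),
    tibble::tibble(colony = 2, t = tt, I_r = poly_vals, I_theta = 0.1,
                   I_Theta = stats::rnorm(8, 0, 0.01), I_a = 0.5))
  sf <- summarize_sample(recs, fit_degree = 6)
  expect_s3_class(sf$fits$I_r$fit, "lm")
  curves <- trend_curves(sf, times = tt)
  expect_equal(curves$fitted[curves$index == "I_r"], poly_vals,
               tolerance = 1e-6)
  gl <- suppressWarnings(glance(sf))  # I_r trajectory is an exact sextic
  expect_true("I_r" %in% gl$index)
})
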