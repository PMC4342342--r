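# Shared battery of inputs exercised by the conservation/normalisation
# property tests.
metric_battery <- function() {
  list(
    clusters = four_cluster_pattern(21, 150),
    disk = random_disk(0.08, R = 40, seed = 11),
    annulus = random_annulus(0.12, R_A = 15, R = 40, seed = 12),
    sparse = random_test_grid(n = 37, R = 25, seed = 13)
  )
}

test_that("counts are conserved and normalisations are exact for every input", {
  for (g in metric_battery()) {
    n <- occupied_count(g)
    rad <- radial_metric(g, 17)
    expect_identical(sum(rad$count), n)
    # weighted radial normalisation: sum of value * expected returns n
    expect_equal(sum(rad$value * rad$expected), n)

    ang <- angular_metric(g, 24)
    expect_identical(sum(ang$count), n)
    expect_equal(mean(ang$value), 1)

    pc <- suppressMessages(pair_correlation_metric(g, 19))
    ns <- signal_meta(pc)$n_s  # sites at the exact centre are excluded
    expect_identical(sum(pc$count), as.integer(ns * (ns - 1) / 2))
    expect_equal(mean(pc$value), 1)
  }
})

test_that("brute-force binning reproduces all three metrics bin-for-bin", {
  for (seed in 1:5) {
    g <- random_test_grid(n = 40 + 30 * seed, R = 12 + 3 * seed, seed = seed)
    expect_identical(radial_metric(g, 11)$count, brute_radial_counts(g, 11))
    expect_identical(angular_metric(g, 14)$count, brute_angular_counts(g, 14))
    expect_identical(pair_correlation_metric(g, 13)$count, brute_pair_counts(g, 13))
  }
  # annular domain too
  ga <- extract_annulus(random_test_grid(n = 120, R = 20, seed = 9), 8)
  expect_identical(radial_metric(ga, 9)$count, brute_radial_counts(ga, 9))
})

test_that("a fully occupied disk has radial metric near 1 in every bin", {
  half <- 60
  gdf <- expand.grid(x = -half:half, y = -half:half)
  gdf <- gdf[gdf$x^2 + gdf$y^2 <= 60^2, ]
  g <- occupancy_grid(gdf, centre = c(0, 0), R = 60)
  rad <- radial_metric(g, 12)
  expect_true(all(abs(rad$value - 1) < 0.15))
})

test_that("rotation by 90 degrees preserves F_r and F_Theta and shifts F_theta", {
  g <- random_test_grid(n = 150, R = 30, seed = 21)
  rot <- occupancy_grid(tibble::tibble(x = -g$sites$y, y = g$sites$x),
                        centre = c(0, 0), R = g$R)
  expect_equal(radial_metric(g, 15)$value, radial_metric(rot, 15)$value)
  M <- 16
  f1 <- angular_metric(g, M)$value
  f2 <- angular_metric(rot, M)$value
  # rotation by pi/2 cyclically advances the bins by M/4
  expect_equal(f2, f1[((seq_len(M) - 1 - M / 4) %% M) + 1])
  expect_equal(pair_correlation_metric(g, 12)$value,
               pair_correlation_metric(rot, 12)$value)
})

test_that("perpendicular position vectors give a pair angle of exactly 90 degrees", {
  g <- occupancy_grid(data.frame(x = c(1, 0), y = c(0, 1)), centre = c(0, 0))
  pc <- pair_correlation_metric(g, 180)
  expect_identical(sum(pc$count), 1L)
  hit <- pc$bin[pc$count == 1L]
  expect_equal(pc$left_edge[hit], pi / 2)  # bin 91 starts exactly at 90 degrees
})

test_that("antipodal pairs land in the closed last pair-angle bin", {
  g <- occupancy_grid(data.frame(x = c(-5, 5), y = c(0, 0)), centre = c(0, 0))
  pc <- pair_correlation_metric(g, 30)
  expect_identical(pc$count[30], 1L)
})

test_that("subsampling is reproducible, recorded, and 'all' matches n_s = n", {
  g <- random_disk(0.1, R = 30, seed = 31)
  n <- occupied_count(g)
  all1 <- pair_correlation_metric(g, 20, n_s = "all")
  all2 <- pair_correlation_metric(g, 20, n_s = n)
  expect_equal(all1$value, all2$value)
  expect_equal(signal_meta(all2)$rho_s, signal_meta(all2)$rho)

  s1 <- pair_correlation_metric(g, 20, n_s = 50, seed = 7)
  s2 <- pair_correlation_metric(g, 20, n_s = 50, seed = 7)
  s3 <- pair_correlation_metric(g, 20, n_s = 50, seed = 8)
  expect_identical(s1$count, s2$count)
  expect_false(identical(s1$count, s3$count))
  expect_identical(sum(s1$count), as.integer(50 * 49 / 2))
  expect_equal(signal_meta(s1)$rho_s, 50 / (pi * g$R^2))
  expect_lt(signal_meta(s1)$rho_s, signal_meta(s1)$rho)
})

test_that("annulus extraction keeps geometry and handles degenerate cases", {
  g <- random_disk(0.1, R = 40, seed = 41)
  ann <- extract_annulus(g, 1e-9)
  expect_equal(occupied_count(ann), occupied_count(g))

  ann2 <- extract_annulus(g, 20)
  pos <- position_set(ann2)
  expect_true(all(pos$r >= 20))
  expect_equal(ann2$R, g$R)

  # disk occupied only inside R/2 leaves an empty annulus
  half <- 40
  gdf <- expand.grid(x = -half:half, y = -half:half)
  core <- gdf[gdf$x^2 + gdf$y^2 <= 20^2, ]
  gc <- occupancy_grid(core, centre = c(0, 0), R = 40)
  expect_error(extract_annulus(gc, 25), "empty annulus")
  expect_error(extract_annulus(g, 45), "degenerate annulus")
})

test_that("a CSR annulus fluctuates about unity in all three metrics", {
  g <- random_annulus(0.1, R_A = 73.5, R = 150, seed = 51)
  rad <- radial_metric(g, 30)
  expect_lt(abs(mean(rad$value) - 1), 0.05)
  expect_true(all(abs(rad$value - 1) < 0.3))
  ang <- angular_metric(g, 30)
  expect_lt(max(abs(ang$value - 1)), 0.3)
  pc <- pair_correlation_metric(g, 30, n_s = 500, seed = 1)
  expect_lt(max(abs(pc$value - 1)), 0.3)
})

test_that("zero-magnitude position vectors are handled by convention", {
  g <- occupancy_grid(data.frame(x = c(0, 3, 0), y = c(0, 0, 4)),
                      centre = c(0, 0))
  expect_message(ang <- angular_metric(g, 8), "zero-magnitude")
  expect_identical(sum(ang$count), 3L)  # centre site assigned theta = 0
  expect_message(pc <- pair_correlation_metric(g, 18), "excluded from pairs")
  expect_identical(sum(pc$count), 1L)   # only the (3,0)-(0,4) pair remains
})

test_that("metric contracts reject invalid inputs", {
  empty <- grid_from_matrix(matrix(0L, 5, 5), centre = c(3, 3))
  expect_error(radial_metric(empty, 10), "empty domain")
  expect_error(angular_metric(empty, 10), "empty domain")
  single <- occupancy_grid(data.frame(x = 1, y = 0), centre = c(0, 0))
  expect_error(pair_correlation_metric(single, 10), "insufficient sites")
})
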