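test_that("random disks occupy exactly the requested number of sites, reproducibly", {
  g <- random_disk(0.1, R = 150, seed = 1)
  expect_equal(occupied_count(g), round(0.1 * pi * 150^2))  # 7069
  expect_true(all(position_set(g)$r <= 150))

  g2 <- random_disk(0.1, R = 150, seed = 1)
  expect_identical(g$sites, g2$sites)
  g3 <- random_disk(0.1, R = 150, seed = 2)
  expect_false(identical(g$sites, g3$sites))
  expect_equal(occupied_count(g3), occupied_count(g))

  expect_error(random_disk(1.5, R = 3), "density too high")
})

test_that("random annuli have the right count, bounds and full-disk density", {
  g <- random_annulus(0.1, R_A = 73.5, R = 150, seed = 4)
  expect_equal(occupied_count(g), round(0.1 * pi * (150^2 - 73.5^2)))
  pos <- position_set(g)
  expect_true(all(pos$r >= 73.5 & pos$r <= 150))
  # full-disk density of this annulus pattern is about 0.076
  expect_equal(density_summary(g)$rho, 0.076, tolerance = 0.01)
})

test_that("the four-cluster pattern is exact and four-fold symmetric", {
  expect_equal(occupied_count(four_cluster_pattern(1, 150)), 4L)
  g <- four_cluster_pattern(21, 150)
  expect_equal(occupied_count(g), 4L * 21L^2)
  # 90-degree rotation (x, y) -> (-y, x) maps the site set to itself
  rot <- dplyr::arrange(tibble::tibble(x = -g$sites$y, y = g$sites$x), x, y)
  orig <- dplyr::arrange(g$sites, x, y)
  expect_equal(rot$x, orig$x)
  expect_equal(rot$y, orig$y)
  expect_error(four_cluster_pattern(22, 150), "odd")
  expect_error(four_cluster_pattern(107, 150), "exceed domain")
})

test_that("filamentous colonies realise their spec", {
  # no arms, no background: exactly the lattice disk of the core
  core_only <- filamentous_colony(filament_spec(
    R = 60, core_radius = 25, filament_density = 0, background_density = 0,
    seed = 1))
  half <- 60
  gdf <- expand.grid(x = -half:half, y = -half:half)
  n_core <- sum(gdf$x^2 + gdf$y^2 <= 25^2)
  expect_equal(occupied_count(core_only), n_core)
  expect_equal(core_only$R, 25)

  # three full arms at known angles dominate the annulus angular signal
  ang3 <- c(-pi / 2, 0, pi / 2)
  g <- filamentous_colony(filament_spec(
    R = 60, core_radius = 25, filament_angles = ang3, filament_length = 30,
    filament_halfwidth = 0.05, filament_density = 1, background_density = 0,
    seed = 2))
  ann <- extract_annulus(g, 26)
  sig <- angular_metric(ann, 36)
  peaks <- find_angular_peaks(sig, 3)
  expect_equal(sort(round(peaks$theta, 6)),
               sort(round(ang3 + pi / 36, 6)))  # arm centres sit on bin edges

  # reproducibility under the spec seed
  g2 <- filamentous_colony(filament_spec(
    R = 60, core_radius = 25, filament_angles = ang3, filament_length = 30,
    filament_halfwidth = 0.05, filament_density = 1, background_density = 0,
    seed = 2))
  expect_identical(g$sites, g2$sites)
})

test_that("arm and background densities equal gives a CSR-like annulus", {
  g <- filamentous_colony(filament_spec(
    R = 100, core_radius = 40, filament_length = 55,
    filament_density = 0.15, background_density = 0.15, seed = 8))
  ann <- extract_annulus(g, 42)
  pc <- pair_correlation_metric(ann, 30, seed = 1)
  expect_lt(abs(pair_correlation_index(pc)), 0.25)
})

test_that("time courses are nested, flat before onset, and respect zero growth", {
  sp <- filament_spec(R = 80, filament_halfwidth = 0.02,
                      filament_density = 0.9, background_density = 0.01,
                      core_taper = 3, seed = 6)
  tc <- colony_time_course(sp, times = c(20, 60, 100, 140, 180), core0 = 20,
                           core_rate = 0.15, onset = 100, filament_rate = 0.3)
  keys <- lapply(tc$grid, function(g) paste(g$sites$x, g$sites$y))
  for (i in seq_len(nrow(tc) - 1)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  }
  # before onset there are no arms: R tracks the tapered core only
  expect_lt(tc$grid[[2]]$R, 20 + 0.15 * 40 + sp$core_taper + 1e-9)
  # after onset arms extend beyond the core
  expect_gt(tc$grid[[5]]$R, 20 + 0.15 * 160 + sp$core_taper)

  # zero filament growth: occupied sets grow only with the core
  tc0 <- colony_time_course(sp, times = c(120, 160), core0 = 20,
                            core_rate = 0, onset = 100, filament_rate = 0)
  expect_equal(occupied_count(tc0$grid[[1]]), occupied_count(tc0$grid[[2]]))
  expect_error(colony_time_course(sp, times = c(3, 2, 1)), "strictly increasing")
})
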