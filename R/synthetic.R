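# Synthetic pattern generators used to validate the metrics: CSR disks and
# annuli, the regular four-cluster pattern, and parametric filamentous
# colonies and growth time courses.

# All integer lattice sites with R_A <= |v| <= R around the origin.
lattice_sites_in_annulus <- function(R, R_A = 0) {
  half <- ceiling(R)
  xs <- -half:half
  g <- expand.grid(x = xs, y = xs)
  r2 <- g$x^2 + g$y^2
  g[r2 <= R^2 & r2 >= R_A^2, ]
}

# Occupy exactly `n` of the candidate sites uniformly at random; with
# bernoulli = TRUE occupy each site independently with probability p.
sample_sites <- function(candidates, n = NULL, p = NULL, seed = NULL,
                         bernoulli = FALSE) {
  with_seed(seed, {
    if (bernoulli) {
      keep <- stats::runif(nrow(candidates)) < p
      candidates[keep, ]
    } else {
      if (n > nrow(candidates)) abort("density too high: fewer lattice sites than requested n")
      candidates[sample.int(nrow(candidates), n), ]
    }
  })
}

#' Uniform-random (CSR) disk pattern
#'
#' Occupies exactly `n = round(rho * pi * R^2)` distinct lattice sites of
#' the disk of radius `R`, chosen uniformly at random without replacement,
#' so the realised mean-field density matches `rho` as closely as the
#' lattice allows. With `bernoulli = TRUE` each site is instead occupied
#' independently with probability `rho` (so `n` varies between draws).
#'
#' @param rho target mean-field density in (0, 1].
#' @param R domain radius in lattice units.
#' @param seed RNG seed for a reproducible pattern.
#' @param bernoulli use independent per-site occupation instead of
#'   exact-n sampling.
#' @return an [occupancy_grid()] centred at the origin with the given `R`.
#' @examples
#' g <- random_disk(0.1, R = 150, seed = 1)
#' occupied_count(g)  # 7069 = round(0.1 * pi * 150^2)
#' @export
random_disk <- function(rho, R, seed = NULL, bernoulli = FALSE) {
  stopifnot_scalar_number(rho, "rho", positive = TRUE)
  stopifnot_scalar_number(R, "R", positive = TRUE)
  cand <- lattice_sites_in_annulus(R)
  if (nrow(cand) == 0L) abort("no lattice sites inside the disk")
  sites <- sample_sites(cand, n = round(rho * pi * R^2), p = rho,
                        seed = seed, bernoulli = bernoulli)
  occupancy_grid(sites, centre = c(0, 0), R = R)
}

#' Uniform-random (CSR) annulus pattern
#'
#' Occupies exactly `round(rho_A * pi * (R^2 - R_A^2))` lattice sites of
#' the annulus `R_A <= |v| <= R` uniformly at random.
#'
#' @param rho_A target annulus density.
#' @param R_A inner radius, `0 < R_A < R`.
#' @inheritParams random_disk
#' @return an [occupancy_grid()] with `R_A` set.
#' @export
random_annulus <- function(rho_A, R_A, R, seed = NULL, bernoulli = FALSE) {
  stopifnot_scalar_number(rho_A, "rho_A", positive = TRUE)
  stopifnot_scalar_number(R_A, "R_A", positive = TRUE)
  stopifnot_scalar_number(R, "R", positive = TRUE)
  if (R_A >= R) abort("degenerate annulus: need R_A < R")
  cand <- lattice_sites_in_annulus(R, R_A)
  if (nrow(cand) == 0L) abort("no lattice sites inside the annulus")
  sites <- sample_sites(cand, n = round(rho_A * pi * (R^2 - R_A^2)), p = rho_A,
                        seed = seed, bernoulli = bernoulli)
  occupancy_grid(sites, centre = c(0, 0), R = R, R_A = R_A)
}

#' Regular four-cluster validation pattern
#'
#' Four fully occupied axis-aligned `l x l` squares of lattice sites,
#' centred at `(R/2, 0)`, `(0, R/2)`, `(-R/2, 0)` and `(0, -R/2)` — i.e.
#' equally spaced on the circle of radius `R/2` inside a domain of radius
#' `R`. `l` must be odd so each square has an exact central site; the
#' pattern is deterministic and symmetric under 90-degree rotation. With
#' `l = 21, R = 150` it contains `4 * 21^2 = 1764` sites at mean-field
#' density 0.0250.
#'
#' @param l odd side length of each square cluster.
#' @param R domain radius.
#' @return an [occupancy_grid()] centred at the origin.
#' @export
four_cluster_pattern <- function(l = 21, R = 150) {
  stopifnot_scalar_number(l, "l", positive = TRUE)
  stopifnot_scalar_number(R, "R", positive = TRUE)
  if (l %% 2 != 1) abort("`l` must be odd so each cluster has a central lattice site")
  if (R / 2 + l * sqrt(2) / 2 > R) abort("clusters exceed domain: R/2 + l*sqrt(2)/2 must be <= R")
  h <- (l - 1) / 2
  offsets <- expand.grid(dx = -h:h, dy = -h:h)
  centres <- list(c(R / 2, 0), c(0, R / 2), c(-R / 2, 0), c(0, -R / 2))
  sites <- purrr::map_dfr(centres, function(ctr) {
    tibble(x = round(ctr[1]) + offsets$dx, y = round(ctr[2]) + offsets$dy)
  })
  occupancy_grid(sites, centre = c(0, 0), R = R)
}

#' Parametric filamentous-colony specification
#'
#' Describes a phenomenological filamentous colony: a fully occupied
#' central core disk with straight filament arms radiating outward at
#' given directions. Each arm is an angular strip of half-width
#' `filament_halfwidth` extending `filament_length` beyond the core, whose
#' lattice sites are occupied independently with probability
#' `filament_density`; remaining disk sites outside the core are occupied
#' with probability `background_density`. Angular distance to an arm is
#' measured on the circle, so arms near the branch cut at +/- pi behave
#' like any other.
#'
#' The defaults mirror a late-stage pseudohyphal colony at the scale of
#' the validation experiments: domain radius 150 with a core of half that
#' radius, and thin (about 2-pixel-wide at the rim), fully occupied arms.
#'
#' @param R domain radius (default 150).
#' @param core_radius radius of the fully occupied core (default 75).
#' @param filament_angles arm directions in radians in `[-pi, pi)`
#'   (default 8 equally spaced arms).
#' @param filament_length radial extent of the arms beyond the core
#'   (default `R - core_radius`).
#' @param filament_halfwidth angular half-width of each arm in radians
#'   (default 0.008).
#' @param filament_density occupancy probability inside an arm
#'   (default 1).
#' @param background_density occupancy probability elsewhere outside the
#'   core (default 0).
#' @param core_taper width (lattice units) of a ragged rim just outside
#'   the core over which occupancy falls linearly from 1 to 0, emulating
#'   the uneven budding edge of a real colony; 0 (the default) gives a
#'   sharp core boundary.
#' @param seed RNG seed.
#' @return a `filament_spec` list, for [filamentous_colony()].
#' @export
filament_spec <- function(R = 150, core_radius = 75,
                          filament_angles = seq(-pi, pi - pi / 4, by = pi / 4),
                          filament_length = R - core_radius,
                          filament_halfwidth = 0.008,
                          filament_density = 1, background_density = 0,
                          core_taper = 0, seed = NULL) {
  stopifnot_scalar_number(R, "R", positive = TRUE)
  stopifnot_scalar_number(core_radius, "core_radius", positive = TRUE)
  stopifnot_scalar_number(filament_length, "filament_length")
  stopifnot_scalar_number(filament_halfwidth, "filament_halfwidth", positive = TRUE)
  if (core_radius + filament_length > R) {
    abort("core_radius + filament_length must be <= R")
  }
  if (filament_density < 0 || filament_density > 1 ||
      background_density < 0 || background_density > 1) {
    abort("densities must lie in [0, 1]")
  }
  stopifnot_scalar_number(core_taper, "core_taper")
  structure(
    list(R = R, core_radius = core_radius, filament_angles = filament_angles,
         filament_length = filament_length,
         filament_halfwidth = filament_halfwidth,
         filament_density = filament_density,
         background_density = background_density,
         core_taper = core_taper, seed = seed),
    class = "filament_spec"
  )
}

# Occupation rule shared by filamentous_colony() and colony_time_course():
# given per-site uniform draws u (fixed across times so colonies nest),
# compute each site's occupancy probability for core radius rc, per-arm
# filament extents fl and densities dens, and a background envelope radius.
# The probability is the maximum over components, and is nondecreasing in
# (rc, fl, dens, envelope), so growing parameters give nested colonies.
filament_occupied <- function(cand, u, spec, rc, fl, dens, envelope) {
  r <- sqrt(cand$x^2 + cand$y^2)
  theta <- atan2(cand$y, cand$x)
  p <- numeric(nrow(cand))
  # ragged rim: occupancy tapers linearly over core_taper beyond the core
  if (spec$core_taper > 0) {
    band <- r > rc & r <= rc + spec$core_taper
    p[band] <- 1 - (r[band] - rc) / spec$core_taper
  }
  n_arm <- length(spec$filament_angles)
  if (n_arm > 0) {
    fl <- rep_len(fl, n_arm)
    dens <- rep_len(dens, n_arm)
    for (i in seq_len(n_arm)) {
      if (fl[i] <= 0) next
      strip <- r > rc & r <= rc + fl[i] &
        circular_distance(theta, spec$filament_angles[i]) <= spec$filament_halfwidth
      p[strip] <- pmax(p[strip], dens[i])
    }
  }
  if (spec$background_density > 0) {
    bg <- r > rc & r <= envelope
    p[bg] <- pmax(p[bg], spec$background_density)
  }
  r <= rc | u < p
}

#' Generate a filamentous colony
#'
#' Realises a [filament_spec()] as an occupancy grid: the core disk is
#' fully occupied, arm and background sites are occupied with their
#' respective probabilities, reproducibly under the spec's seed.
#'
#' @param spec a [filament_spec()].
#' @return an [occupancy_grid()] centred at the origin. `R` is the maximum
#'   occupied radius (the domain radius of the analysis is defined by the
#'   colony itself, as for a real image).
#' @export
filamentous_colony <- function(spec) {
  stopifnot(inherits(spec, "filament_spec"))
  cand <- lattice_sites_in_annulus(spec$R)
  occ <- with_seed(spec$seed, {
    u <- stats::runif(nrow(cand))
    filament_occupied(cand, u, spec, spec$core_radius, spec$filament_length,
                      spec$filament_density, envelope = spec$R)
  })
  occupancy_grid(cand[occ, ], centre = c(0, 0))
}

#' Synthetic colony growth time course
#'
#' Emulates the growth of a colony that expands uniformly at first and
#' begins filamentous growth at an onset time. Before `onset` the colony
#' is a growing occupied disk (with the spec's ragged `core_taper` rim);
#' afterwards the core keeps growing at `core_rate` while filament arms
#' elongate at `filament_rate`. Two optional refinements emulate how
#' filamentation develops gradually in real colonies: successive arms can
#' switch on one by one (`arm_stagger` hours apart, in the order of
#' `spec$filament_angles`), and each arm's occupancy can ramp linearly
#' from the background level to `spec$filament_density` over `maturation`
#' hours as cells fill the filament in.
#'
#' Per-site random draws are fixed once and every occupancy probability is
#' nondecreasing in time, so the occupied sets are nested (a site, once
#' occupied, stays occupied). Background sites are confined to the radius
#' the colony has reached (core plus longest arm), not the whole domain.
#'
#' @param spec a [filament_spec()] providing the domain, arm geometry,
#'   densities and seed; its `core_radius`/`filament_length` are ignored
#'   in favour of the growth rules below.
#' @param times strictly increasing sampling times in hours.
#' @param core0 core radius at `times[1]` (default 10).
#' @param core_rate core radial growth rate, lattice units per hour.
#' @param onset filamentation onset time in hours.
#' @param filament_rate filament elongation rate, lattice units per hour
#'   after each arm's onset.
#' @param arm_stagger hours between successive arm onsets (default 0:
#'   all arms start at `onset`).
#' @param maturation hours over which an arm's occupancy ramps up to
#'   `filament_density` (default 0: full density immediately).
#' @return a tibble with columns `t` and `grid` (list column of
#'   [occupancy_grid()]s).
#' @export
colony_time_course <- function(spec, times, core0 = 10, core_rate = 0.25,
                               onset = 100, filament_rate = 0.6,
                               arm_stagger = 0, maturation = 0) {
  stopifnot(inherits(spec, "filament_spec"))
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly increasing")
  cand <- lattice_sites_in_annulus(spec$R)
  u <- with_seed(spec$seed, stats::runif(nrow(cand)))
  n_arm <- length(spec$filament_angles)
  arm_onset <- onset + arm_stagger * (seq_len(n_arm) - 1)
  grids <- purrr::map(times, function(t) {
    rc <- min(core0 + core_rate * (t - times[1]), spec$R)
    age <- pmax(t - arm_onset, 0)
    fl <- pmin(filament_rate * age, spec$R - rc - spec$core_taper)
    ramp <- if (maturation > 0) pmin(age / maturation, 1) else as.numeric(age > 0)
    dens <- spec$background_density +
      (spec$filament_density - spec$background_density) * ramp
    envelope <- rc + max(c(spec$core_taper, fl, 0))
    occ <- filament_occupied(cand, u, spec, rc, fl, dens, envelope)
    occupancy_grid(cand[occ, ], centre = c(0, 0))
  })
  tibble(t = times, grid = grids)
}
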