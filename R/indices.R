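#' Radial distance of the crossover to complete spatial randomness
#'
#' A growing colony's radial metric is above 1 (aggregated) through its
#' fully occupied core and below 1 (segregated) through its sparse margin.
#' `find_r_csr()` locates the radial distance at which the signal crosses
#' unity: the last downward crossing after which the signal stays below 1
#' for at least `persistence` consecutive bins (or through the final bin),
#' linearly interpolated between the two bracketing bin midpoints. The
#' persistence requirement makes the estimate robust to single-bin noise
#' while reproducing the clean single-crossing case exactly.
#'
#' Degenerate signals have natural limits: a signal that never exceeds 1
#' gives 0; one that never drops below 1 (uniform growth out to the rim)
#' gives `R`, so the radial index is 0.
#'
#' @param radial_signal a [colony_signal] of kind `"radial"` from a
#'   full-disk domain.
#' @param persistence minimum number of consecutive below-unity bins
#'   required after the crossing (default 3).
#' @return the crossover radius `R_csr` in lattice units.
#' @export
find_r_csr <- function(radial_signal, persistence = 3) {
  stopifnot(inherits(radial_signal, "colony_signal"))
  if (!identical(attr(radial_signal, "kind"), "radial")) {
    abort("find_r_csr() requires a radial-metric signal")
  }
  stopifnot_scalar_number(persistence, "persistence", positive = TRUE)
  v <- radial_signal$value
  m <- radial_signal$midpoint
  L <- length(v)
  if (L < 2L) abort("signal too short: need at least 2 radial bins")
  R <- signal_meta(radial_signal)$R
  if (all(v < 1)) return(0)
  below <- v < 1
  # run length of consecutive below-unity bins starting at each index
  run <- integer(L)
  run[L] <- as.integer(below[L])
  for (i in (L - 1L):1L) run[i] <- if (below[i]) run[i + 1L] + 1L else 0L
  cross <- which(!below[-L] & below[-1L])            # v[i] >= 1 > v[i+1]
  persistent <- cross[run[cross + 1L] >= pmin(persistence, L - cross)]
  if (length(persistent) == 0L) return(R)
  i <- max(persistent)
  # linear interpolation of the unity crossing between bin midpoints
  m[i] + (v[i] - 1) / (v[i] - v[i + 1L]) * (m[i + 1L] - m[i])
}

#' Radial index of filamentation
#'
#' `I_r = 1 - R_csr / R`: 0 when the colony is uniform out to its rim
#' (`R_csr = R`), approaching 1 as the over-dispersed filamentous margin
#' comes to dominate the radial extent.
#'
#' @param R_csr crossover radius from [find_r_csr()].
#' @param R maximum radial distance of the colony.
#' @return a value in `[0, 1]`.
#' @export
radial_index <- function(R_csr, R) {
  stopifnot_scalar_number(R_csr, "R_csr")
  stopifnot_scalar_number(R, "R", positive = TRUE)
  if (R_csr < 0 || R_csr > R) abort("inconsistent radii: need 0 <= R_csr <= R")
  1 - R_csr / R
}

#' Pair-correlation index of aggregation
#'
#' `I_Theta = F_Theta(1) - 1`: the excess of the first pair-angle bin over
#' its CSR expectation. Pairs at near-zero pair angle lie along the same
#' ray from the colony centre, so a positive index measures localised
#' aggregation of occupied sites into common filaments; a CSR pattern
#' gives 0 up to sampling error.
#'
#' @param pair_signal a [colony_signal] of kind `"pair_angle"`.
#' @return the first bin's value minus 1 (>= -1).
#' @export
pair_correlation_index <- function(pair_signal) {
  stopifnot(inherits(pair_signal, "colony_signal"))
  if (!identical(attr(pair_signal, "kind"), "pair_angle")) {
    abort("pair_correlation_index() requires a pair-angle signal")
  }
  pair_signal$value[1] - 1
}

#' Area-fraction index
#'
#' `I_a = 1 - rho`: one minus the mean-field density of the full circular
#' domain. It tracks the overall sparsity of the colony but carries no
#' information about where the unoccupied area lies.
#'
#' @param density a one-row tibble from [density_summary()] (or any list
#'   with an element `rho`).
#' @return a value in `[0, 1]`; densities above 1 (possible from
#'   discretisation at very small `R`) are clamped with a warning.
#' @export
area_fraction_index <- function(density) {
  rho <- density$rho
  stopifnot_scalar_number(rho, "rho")
  if (rho > 1) {
    warn("rho > 1 from lattice discretisation; clamping to 1")
    rho <- 1
  }
  1 - rho
}

#' Locate the top local maxima of an angular signal
#'
#' Finds circular local maxima (strictly greater than both neighbours,
#' with wrap-around) of an angular-metric signal and returns the bin
#' midpoints of the `n_peaks` largest, e.g. to recover filament
#' directions.
#'
#' @param signal a [colony_signal] of kind `"angular"`.
#' @param n_peaks number of peaks to return.
#' @return a tibble with columns `theta` (bin midpoint), `value`, ordered
#'   by decreasing value; fewer rows if the signal has fewer local maxima.
#' @export
find_angular_peaks <- function(signal, n_peaks) {
  stopifnot(inherits(signal, "colony_signal"))
  if (!identical(attr(signal, "kind"), "angular")) {
    abort("find_angular_peaks() requires an angular-metric signal")
  }
  v <- signal$value
  M <- length(v)
  left <- v[c(M, seq_len(M - 1L))]
  right <- v[c(seq_len(M)[-1L], 1L)]
  is_peak <- v > 0 & v >= left & v >= right & (v > left | v > right)
  peaks <- tibble(theta = signal$midpoint[is_peak], value = v[is_peak])
  peaks <- peaks[order(-peaks$value), ]
  head(peaks, n_peaks)
}

#' Full spatial analysis of one colony image
#'
#' Runs the complete per-colony workflow: the radial metric on the full
#' disk, detection of the CSR crossover radius `R_csr`, extraction of the
#' filament-dominated annulus `R_csr <= |v| <= R`, the angular metric and
#' its spectrum on the annulus, the angular pair-correlation metric on the
#' annulus, and assembly of the four scalar indices.
#'
#' When the colony is uniform out to its rim the annulus is empty (or
#' `R_csr = R`); the angular and pair-correlation indices are then 0 and
#' the record is flagged via `annulus_empty`.
#'
#' @param grid an [occupancy_grid()] with at least one occupied site.
#' @param L radial bin count (default chosen so the bin width is about
#'   `R/180`).
#' @param M angular bin count (default 200).
#' @param N pair-angle bin count (default 200).
#' @param n_s pair-metric subsample size; pairs are exhaustive whenever
#'   the annulus holds at most `max(n_s, 5000)` sites (default 1000).
#' @param persistence see [find_r_csr()] (default 3).
#' @param seed RNG seed for pair subsampling.
#' @param t optional time label (hours) copied into the record.
#' @return a one-row tibble: `t`, `n`, `R`, `R_csr` (both in physical
#'   units via the grid's `length_scale`), `I_r`, `I_theta`, `I_Theta`,
#'   `I_a`, `rho`, `annulus_empty`.
#' @export
analyze_colony <- function(grid, L = 180, M = 200, N = 200, n_s = 1000,
                           persistence = 3, seed = NULL, t = NA_real_) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (grid$n == 0L) abort("empty colony: no occupied sites")
  dens <- density_summary(grid)
  rad <- radial_metric(grid, L)
  R_csr <- find_r_csr(rad, persistence = persistence)
  I_r <- radial_index(R_csr, grid$R)
  annulus_empty <- FALSE
  I_theta <- 0
  I_Theta <- 0
  if (R_csr < grid$R) {
    ann <- tryCatch(extract_annulus(grid, max(R_csr, 1e-9)),
                    error = function(e) NULL)
    if (is.null(ann) || ann$n < 2L) {
      annulus_empty <- TRUE
    } else {
      ang <- angular_metric(ann, M)
      I_theta <- angular_index(angular_spectrum(ang))
      use_ns <- if (ann$n <= max(n_s, 5000)) "all" else n_s
      pc <- pair_correlation_metric(ann, N, n_s = use_ns, seed = seed)
      I_Theta <- pair_correlation_index(pc)
    }
  } else {
    annulus_empty <- TRUE
  }
  tibble(
    t = t, n = grid$n,
    R = grid$R * grid$length_scale,
    R_csr = R_csr * grid$length_scale,
    I_r = I_r, I_theta = I_theta, I_Theta = I_Theta,
    I_a = area_fraction_index(dens),
    rho = dens$rho, annulus_empty = annulus_empty
  )
}

#' Average index trajectories over a sample of colonies
#'
#' Given per-colony index records (one row per colony and time, as stacked
#' [analyze_colony()] output with a `colony` column), computes the per-time
#' mean and standard error of the mean of each index, and fits a sextic
#' (degree-6) least-squares polynomial to each mean trajectory for display
#' of the trend. The fits never feed back into any index.
#'
#' @param records a data frame with columns `colony`, `t`, and the index
#'   columns `I_r`, `I_theta`, `I_Theta`, `I_a` (plus optionally `R`,
#'   `R_csr`).
#' @param fit_degree polynomial degree for the trend fit (default 6); `NA`
#'   suppresses fitting, as does a time grid too short to support it.
#' @return an object of class `colony_sample_summary`: use [tidy()] for
#'   the per-time mean/SEM table, [glance()] for fit diagnostics, and
#'   [autoplot()] to plot the trajectories.
#' @export
summarize_sample <- function(records, fit_degree = 6) {
  records <- as_tibble(records)
  needed <- c("colony", "t", "I_r", "I_theta", "I_Theta", "I_a")
  if (!all(needed %in% names(records))) {
    abort(sprintf("records must have columns: %s", paste(needed, collapse = ", ")))
  }
  counts <- dplyr::count(records, .data$t)
  per_colony <- dplyr::count(records, .data$colony)
  if (length(unique(per_colony$n)) != 1L ||
      nrow(counts) * length(unique(records$colony)) != nrow(records)) {
    abort("inconsistent time points: every colony must be observed at every time")
  }
  if (nrow(records) < 2L || all(counts$n < 2L)) {
    abort("need at least 2 colonies sharing time points")
  }
  extra <- intersect(c("R", "R_csr"), names(records))
  long <- tidyr::pivot_longer(
    records[, c("colony", "t", "I_r", "I_theta", "I_Theta", "I_a", extra)],
    cols = -c("colony", "t"), names_to = "index", values_to = "value"
  )
  summary <- long |>
    dplyr::group_by(.data$index, .data$t) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      n_colonies = dplyr::n(),
      .groups = "drop"
    )
  fits <- NULL
  n_times <- length(unique(records$t))
  if (!is.na(fit_degree) && n_times > fit_degree) {
    fits <- summary |>
      dplyr::group_by(.data$index) |>
      dplyr::group_map(function(d, key) {
        fit <- lm(mean ~ poly(t, fit_degree, raw = TRUE), data = d)
        list(index = key$index[[1]], fit = fit)
      })
    names(fits) <- vapply(fits, `[[`, "", "index")
  }
  structure(
    list(summary = summary, fits = fits, times = sort(unique(records$t)),
         n_colonies = length(unique(records$colony)), fit_degree = fit_degree),
    class = "colony_sample_summary"
  )
}

#' @export
print.colony_sample_summary <- function(x, ...) {
  cat(sprintf("<colony_sample_summary> %d colonies, %d time points\n",
              x$n_colonies, length(x$times)))
  print(tidy(x))
  invisible(x)
}

#' @rdname summarize_sample
#' @param x a `colony_sample_summary`.
#' @param ... unused.
#' @export
tidy.colony_sample_summary <- function(x, ...) {
  x$summary
}

#' @rdname summarize_sample
#' @export
glance.colony_sample_summary <- function(x, ...) {
  if (is.null(x$fits)) {
    return(tibble(index = character(), r.squared = numeric(), sigma = numeric()))
  }
  purrr::map_dfr(x$fits, function(f) {
    s <- summary(f$fit)
    tibble(index = f$index, r.squared = s$r.squared, sigma = s$sigma,
           df.residual = f$fit$df.residual)
  })
}

#' Evaluate the fitted trend polynomials of a sample summary
#'
#' @param x a `colony_sample_summary` with fits.
#' @param times time points at which to evaluate (default: 200 points
#'   spanning the observed range).
#' @return a tibble with columns `index`, `t`, `fitted`.
#' @export
trend_curves <- function(x, times = NULL) {
  stopifnot(inherits(x, "colony_sample_summary"))
  if (is.null(x$fits)) abort("summary has no trend fits")
  if (is.null(times)) times <- seq(min(x$times), max(x$times), length.out = 200)
  purrr::map_dfr(x$fits, function(f) {
    tibble(index = f$index, t = times,
           fitted = unname(predict(f$fit, newdata = data.frame(t = times))))
  })
}
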