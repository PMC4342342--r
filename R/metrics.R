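#' Binned spatial-metric signals
#'
#' The three metrics (radial, angular, angular pair-correlation) are
#' returned as tibbles of class `colony_signal` with one row per bin and
#' columns:
#' \describe{
#'   \item{bin}{bin index (1-based)}
#'   \item{left_edge}{left bin edge (radial distance, angle theta, or pair
#'     angle Theta)}
#'   \item{midpoint}{bin midpoint}
#'   \item{count}{raw count in the bin}
#'   \item{expected}{expected count under complete spatial randomness (CSR)}
#'   \item{value}{the CSR-normalised metric, `count / expected`}
#' }
#' Metadata (kind, bin count and width, n, rho, R, R_A, and for the pair
#' metric n_s, rho_s and the subsampling seed) is carried in attributes;
#' see [signal_meta()].
#'
#' @name colony_signal
NULL

new_colony_signal <- function(df, kind, meta) {
  out <- as_tibble(df)
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta
  class(out) <- c("colony_signal", class(out))
  out
}

#' Metadata of a metric signal
#'
#' @param signal a `colony_signal`.
#' @return a named list: `kind`, `bin_count`, `bin_width`, `n`, `rho`, `R`,
#'   `R_A`, plus `n_s`, `rho_s`, `seed` for the pair-correlation metric.
#' @export
signal_meta <- function(signal) {
  stopifnot(inherits(signal, "colony_signal"))
  c(list(kind = attr(signal, "kind")), attr(signal, "meta"))
}

#' @export
print.colony_signal <- function(x, ...) {
  m <- signal_meta(x)
  cat(sprintf("<colony_signal: %s> %d bins, n = %d, rho = %.4g\n",
              m$kind, m$bin_count, m$n, m$rho))
  NextMethod()
}

# Evaluate positions once and run the shared empty-domain contract.
signal_positions <- function(grid) {
  if (grid$n == 0L) abort("empty domain: metric undefined for n = 0")
  position_set(grid)
}

#' Radial metric: CSR-normalised occupied counts in concentric annuli
#'
#' Counts occupied sites in `L` equal-width radial bins spanning
#' `[R_A, R)` (last bin closed, so the site defining `R` is counted) and
#' divides each count by its CSR expectation: the bin's annular area times
#' the mean-field density (`rho` for a disk, the annulus density `rho_A`
#' for an annular domain). Values above 1 indicate aggregation
#' (under-dispersion), below 1 segregation (over-dispersion) relative to a
#' uniformly random pattern at the same density.
#'
#' @param grid an [occupancy_grid()] with at least one occupied site.
#' @param L number of radial bins.
#' @return a [colony_signal] tibble with `L` rows.
#' @export
radial_metric <- function(grid, L) {
  stopifnot_scalar_number(L, "L", positive = TRUE)
  pos <- signal_positions(grid)
  R <- grid$R; R_A <- grid$R_A
  delta <- (R - R_A) / L
  idx <- bin_index(pos$r, R_A, R, L)
  counts <- tabulate(idx, nbins = L)
  i <- seq_len(L)
  edges <- R_A + delta * (i - 1)
  # annular bin area; reduces to pi * delta^2 * (2i - 1) when R_A = 0
  area <- pi * ((R_A + i * delta)^2 - (R_A + (i - 1) * delta)^2)
  dens <- density_summary(grid)
  expected <- area * dens$rho_A
  new_colony_signal(
    tibble(bin = i, left_edge = edges, midpoint = edges + delta / 2,
           count = counts, expected = expected, value = counts / expected),
    kind = "radial",
    meta = list(bin_count = L, bin_width = delta, n = grid$n,
                rho = dens$rho, rho_A = dens$rho_A, R = R, R_A = R_A)
  )
}

#' Angular metric: CSR-normalised occupied counts in circular sectors
#'
#' Bins the principal argument of each occupied site's position vector into
#' `M` equal sectors partitioning `[-pi, pi)` and divides the counts by the
#' CSR expectation per sector, `rho * Delta_theta * R^2 / 2`. For annular
#' domains the same normalisation is used with `rho` the full-disk density
#' of the retained sites, so the sector values remain comparable across
#' domains. The unweighted mean of the values is exactly 1.
#'
#' A site falling exactly on the centre has no direction; it is assigned
#' argument 0 by convention and the event is reported via a message.
#'
#' @param grid an [occupancy_grid()] with at least one occupied site.
#' @param M number of angular bins.
#' @return a [colony_signal] tibble with `M` rows.
#' @export
angular_metric <- function(grid, M) {
  stopifnot_scalar_number(M, "M", positive = TRUE)
  pos <- signal_positions(grid)
  n_zero <- sum(pos$r == 0)
  if (n_zero > 0) {
    inform(sprintf("angular_metric: %d zero-magnitude position vector(s) assigned theta = 0", n_zero))
  }
  delta <- 2 * pi / M
  idx <- bin_index(pos$theta, -pi, pi, M)
  counts <- tabulate(idx, nbins = M)
  dens <- density_summary(grid)
  expected <- rep(0.5 * dens$rho * delta * grid$R^2, M)
  j <- seq_len(M)
  edges <- -pi + delta * (j - 1)
  new_colony_signal(
    tibble(bin = j, left_edge = edges, midpoint = edges + delta / 2,
           count = counts, expected = expected, value = counts / expected),
    kind = "angular",
    meta = list(bin_count = M, bin_width = delta, n = grid$n,
                rho = dens$rho, R = grid$R, R_A = grid$R_A,
                n_zero_vectors = n_zero)
  )
}

# Run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Angular pair-correlation metric
#'
#' For every unordered pair of distinct occupied sites, the pair angle
#' `Theta = acos(v1 . v2 / (|v1||v2|))` in `[0, pi]` is the angle between
#' their position vectors at the domain centre. Pair angles are binned into
#' `N` equal widths over `[0, pi]` (last bin closed, so antipodal pairs at
#' exactly pi are counted) and normalised by the CSR expectation
#' `rho_s * Delta_Theta * R^2 * (pi * rho_s * R^2 - 1) / 2`, which equals
#' the total pair count divided by `N`. The unweighted mean of the values
#' is exactly 1.
#'
#' Because the pair count grows as O(n^2), a random subsample of `n_s`
#' sites can be analysed instead; the normalisation then uses the effective
#' density `rho_s = n_s / (pi R^2)`. Sampling is without replacement from
#' the deterministic site order, so a given `seed` reproduces the subset.
#'
#' @param grid an [occupancy_grid()] with at least 2 occupied sites.
#' @param N number of pair-angle bins.
#' @param n_s subsample size, or `"all"` (the default) for all sites.
#' @param seed RNG seed for the subsample; required for reproducibility
#'   when `n_s < n`.
#' @return a [colony_signal] tibble with `N` rows.
#' @export
pair_correlation_metric <- function(grid, N, n_s = "all", seed = NULL) {
  stopifnot_scalar_number(N, "N", positive = TRUE)
  pos <- signal_positions(grid)
  zero <- pos$r == 0
  if (any(zero)) {
    inform(sprintf("pair_correlation_metric: %d zero-magnitude vector(s) excluded from pairs", sum(zero)))
    pos <- pos[!zero, ]
  }
  n_avail <- nrow(pos)
  if (identical(n_s, "all")) {
    n_s_num <- n_avail
  } else {
    stopifnot_scalar_number(n_s, "n_s", positive = TRUE)
    n_s_num <- min(as.integer(n_s), n_avail)
  }
  if (n_s_num < 2L) abort("insufficient sites: pair metric needs at least 2")
  if (n_s_num < n_avail) {
    keep <- with_seed(seed, sample.int(n_avail, n_s_num))
    pos <- pos[keep, ]
  }
  u <- cbind(pos$x, pos$y) / pos$r
  g <- tcrossprod(u)
  ang <- acos(clamp(g[upper.tri(g)]))
  delta <- pi / N
  idx <- bin_index(ang, 0, pi, N)
  counts <- tabulate(idx, nbins = N)
  R <- grid$R
  rho_s <- n_s_num / (pi * R^2)
  expected <- rep(0.5 * rho_s * delta * R^2 * (pi * rho_s * R^2 - 1), N)
  k <- seq_len(N)
  edges <- delta * (k - 1)
  dens <- density_summary(grid)
  new_colony_signal(
    tibble(bin = k, left_edge = edges, midpoint = edges + delta / 2,
           count = counts, expected = expected, value = counts / expected),
    kind = "pair_angle",
    meta = list(bin_count = N, bin_width = delta, n = grid$n,
                rho = dens$rho, rho_s = rho_s, n_s = n_s_num,
                seed = seed, R = R, R_A = grid$R_A)
  )
}

#' Extract the annular outer region of a grid
#'
#' Restricts a grid to the annulus `R_inner <= |v| <= R`, keeping the same
#' centre and outer radius. The returned grid's annulus density `rho_A`
#' drives the radial normalisation, while its full-disk `rho` (recomputed
#' from the retained sites) drives the angular metrics, so the outer margin
#' of a colony can be analysed in isolation from its fully occupied core.
#'
#' @param grid an [occupancy_grid()].
#' @param R_inner inner radius, `0 < R_inner < R`.
#' @return an `occupancy_grid` with `R_A = R_inner`.
#' @export
extract_annulus <- function(grid, R_inner) {
  stopifnot(inherits(grid, "occupancy_grid"))
  stopifnot_scalar_number(R_inner, "R_inner", positive = TRUE)
  if (R_inner >= grid$R) abort("degenerate annulus: R_inner must be < R")
  pos <- position_set(grid)
  keep <- pos$r >= R_inner
  if (!any(keep)) abort("empty annulus: no occupied sites with |v| >= R_inner")
  occupancy_grid(grid$sites[keep, ], centre = grid$centre, R = grid$R,
                 R_A = R_inner, length_scale = grid$length_scale)
}
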