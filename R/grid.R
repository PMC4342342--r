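#' Occupancy grids: binary colony lattices on circular or annular domains
#'
#' An `occupancy_grid` represents a single colony (at one time point) as the
#' set of occupied integer lattice sites inside a circular domain of radius
#' `R`, or an annular domain with inner radius `R_A`. Position vectors are
#' measured from the domain centre, with x rightward and y upward. All
#' computation is in lattice units; `length_scale` (physical units per
#' lattice spacing, e.g. microns/pixel) is applied only when distances are
#' reported.
#'
#' @param sites a data frame with integer columns `x`, `y`: absolute lattice
#'   coordinates of the occupied sites.
#' @param centre numeric length-2, the domain centre in the same absolute
#'   coordinates (may be non-integer).
#' @param R domain radius in lattice units; defaults to the maximum distance
#'   of an occupied site from the centre.
#' @param R_A inner (hole) radius for annular domains; 0 for a full disk.
#' @param length_scale physical units per lattice spacing (default 1).
#' @return an object of class `occupancy_grid` with fields `sites` (tibble),
#'   `centre`, `R`, `R_A`, `n`, `length_scale`.
#' @seealso [grid_from_matrix()], [position_set()], [density_summary()]
#' @export
occupancy_grid <- function(sites, centre, R = NULL, R_A = 0, length_scale = 1) {
  sites <- as_tibble(sites[, c("x", "y")])
  if (length(centre) != 2L || !is.numeric(centre)) {
    abort("`centre` must be a numeric pair (x, y).")
  }
  centre <- as.numeric(centre)
  r <- sqrt((sites$x - centre[1])^2 + (sites$y - centre[2])^2)
  if (is.null(R)) {
    if (nrow(sites) == 0L) abort("empty colony: cannot infer R from no occupied sites")
    R <- max(r)
  }
  stopifnot_scalar_number(R, "R", positive = TRUE)
  stopifnot_scalar_number(R_A, "R_A")
  if (R_A < 0 || R_A >= R) abort("degenerate annulus: need 0 <= R_A < R")
  if (any(r < R_A)) abort("site inside annulus hole: occupied site with |v| < R_A")
  # tiny tolerance: R may equal max(r) up to rounding when supplied explicitly
  if (any(r > R * (1 + 1e-12))) abort("occupied site outside domain radius R")
  structure(
    list(
      sites = sites, centre = centre, R = R, R_A = R_A,
      n = nrow(sites), length_scale = length_scale
    ),
    class = "occupancy_grid"
  )
}

#' Build an occupancy grid from a binary matrix
#'
#' Converts a 0/1 matrix (a binary image mask) into an [occupancy_grid()].
#' Matrix rows are image rows top-to-bottom; the grid coordinate convention
#' is x rightward (columns) and y upward, so row 1 has the largest y. With
#' `centre = "auto"` the centre is the (real-valued, unrounded) centre of
#' mass of the occupied sites and `R` is the maximum distance from the
#' centre to an occupied site.
#'
#' @param m a matrix whose entries are exactly 0 or 1 (or logical).
#' @param centre `"auto"` (centre of mass) or a numeric pair in (x, y)
#'   lattice coordinates (column, row-from-bottom).
#' @param R_A inner annulus radius; occupied sites closer than `R_A` to the
#'   centre are an error.
#' @param length_scale physical units per pixel.
#' @return an `occupancy_grid`.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 8] <- 1  # one site at (3, 0) from centre (5,5)
#' g <- grid_from_matrix(m, centre = c(5, 5))
#' g$R
#' @export
grid_from_matrix <- function(m, centre = "auto", R_A = 0, length_scale = 1) {
  if (is.logical(m)) storage.mode(m) <- "integer"
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    abort("`m` must be a binary (0/1) matrix.")
  }
  occ <- which(m == 1, arr.ind = TRUE)
  # row-major scan order (row 1 first, columns left to right) so downstream
  # subsampling under a seed is reproducible
  occ <- occ[order(occ[, 1], occ[, 2]), , drop = FALSE]
  x <- as.numeric(occ[, 2])
  y <- as.numeric(nrow(m) - occ[, 1] + 1L)  # y upward
  if (identical(centre, "auto")) {
    if (length(x) == 0L) abort("empty colony: no occupied sites for centre = \"auto\"")
    centre <- c(mean(x), mean(y))
  }
  # empty grid with an explicit centre is valid (rho = 0); take R as the
  # distance to the farthest matrix corner so the domain covers the image
  R <- NULL
  if (length(x) == 0L) {
    cx <- c(1, ncol(m)); cy <- c(1, nrow(m))
    R <- max(sqrt(outer((cx - centre[1])^2, (cy - centre[2])^2, `+`)))
  }
  occupancy_grid(tibble(x = x, y = y), centre = centre, R = R,
                 R_A = R_A, length_scale = length_scale)
}

#' @export
print.occupancy_grid <- function(x, ...) {
  dom <- if (x$R_A > 0) sprintf("annulus [%.4g, %.4g]", x$R_A, x$R) else sprintf("disk R = %.4g", x$R)
  cat(sprintf("<occupancy_grid> %s sites on %s (centre %.2f, %.2f)\n",
              format(x$n, big.mark = ","), dom, x$centre[1], x$centre[2]))
  invisible(x)
}

#' Number of occupied lattice sites
#'
#' @param grid an `occupancy_grid`.
#' @return the occupied-site count n.
#' @export
occupied_count <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  grid$n
}

#' Mean-field densities of a grid
#'
#' Returns the occupied count `n`, the full-disk mean-field density
#' `rho = n / (pi R^2)` and the annulus density
#' `rho_A = n / (pi (R^2 - R_A^2))`; the two are equal for a full disk.
#'
#' @param grid an `occupancy_grid`.
#' @return a one-row tibble with columns `n`, `rho`, `rho_A`, `R`, `R_A`.
#' @export
density_summary <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (grid$R_A >= grid$R) abort("degenerate annulus")
  tibble(
    n = grid$n,
    rho = grid$n / (pi * grid$R^2),
    rho_A = grid$n / (pi * (grid$R^2 - grid$R_A^2)),
    R = grid$R,
    R_A = grid$R_A
  )
}

#' Position vectors of occupied sites
#'
#' One row per occupied site, expressed relative to the domain centre, in
#' deterministic row-major scan order. `r` is the magnitude and `theta` the
#' principal argument in [-pi, pi).
#'
#' @param grid an `occupancy_grid`.
#' @return a tibble with columns `x`, `y`, `r`, `theta`.
#' @export
position_set <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  x <- grid$sites$x - grid$centre[1]
  y <- grid$sites$y - grid$centre[2]
  theta <- atan2(y, x)
  # atan2 returns pi for (-r, 0); fold onto [-pi, pi)
  theta[theta >= pi] <- -pi
  tibble(x = x, y = y, r = sqrt(x^2 + y^2), theta = theta)
}

#' Reconstruct the binary occupancy matrix of a grid
#'
#' Inverse of [grid_from_matrix()] up to the bounding box: returns a 0/1
#' matrix covering the domain square, with matrix row 1 at the top
#' (largest y).
#'
#' @param grid an `occupancy_grid`.
#' @return a binary integer matrix.
#' @export
as_occupancy_matrix <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  half <- ceiling(grid$R) + 1L
  x0 <- floor(grid$centre[1]) - half
  y1 <- ceiling(grid$centre[2]) + half
  nc <- 2L * half + 2L
  m <- matrix(0L, nrow = nc, ncol = nc)
  if (grid$n > 0L) {
    col <- round(grid$sites$x) - x0
    row <- y1 - round(grid$sites$y) + 1L
    m[cbind(row, col)] <- 1L
  }
  m
}
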