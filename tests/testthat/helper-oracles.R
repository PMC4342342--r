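# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately use naive per-site / per-pair
# loops and explicit if-chains so they share no code with the package's
# vectorised binning.

brute_radial_counts <- function(grid, L) {
  pos <- position_set(grid)
  delta <- (grid$R - grid$R_A) / L
  counts <- integer(L)
  for (r in pos$r) {
    i <- 1L
    while (i < L && r >= grid$R_A + i * delta) i <- i + 1L
    counts[i] <- counts[i] + 1L
  }
  counts
}

brute_angular_counts <- function(grid, M) {
  pos <- position_set(grid)
  delta <- 2 * pi / M
  counts <- integer(M)
  for (th in pos$theta) {
    j <- 1L
    while (j < M && th >= -pi + j * delta) j <- j + 1L
    counts[j] <- counts[j] + 1L
  }
  counts
}

brute_pair_counts <- function(grid, N) {
  pos <- position_set(grid)
  delta <- pi / N
  counts <- integer(N)
  n <- nrow(pos)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dot <- pos$x[i] * pos$x[j] + pos$y[i] * pos$y[j]
      cosang <- dot / (pos$r[i] * pos$r[j])
      if (cosang > 1) cosang <- 1
      if (cosang < -1) cosang <- -1
      ang <- acos(cosang)
      k <- 1L
      while (k < N && ang >= k * delta) k <- k + 1L
      counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# Direct evaluation of the angular DFT sum, one coefficient at a time.
brute_dft_coef <- function(values, x, k, M) {
  ck <- if (abs(k) == M / 2) 2 else 1
  sum(values * exp(-1i * k * x)) / (M * ck)
}

# A random sparse grid with exactly n occupied lattice sites in the disk.
random_test_grid <- function(n, R, seed) {
  set.seed(seed)
  half <- ceiling(R)
  g <- expand.grid(x = -half:half, y = -half:half)
  r2 <- g$x^2 + g$y^2
  g <- g[r2 <= R^2 & r2 > 0, ]  # exclude the origin: no zero-magnitude vectors
  occupancy_grid(g[sample.int(nrow(g), n), ], centre = c(0, 0), R = R)
}

# Build a colony_signal by hand (for synthetic radial/angular inputs with
# known values, independent of any grid).
make_signal <- function(kind, values, R = 150, R_A = 0, n = 1) {
  L <- length(values)
  if (kind == "radial") {
    delta <- (R - R_A) / L
    edges <- R_A + delta * (seq_len(L) - 1)
  } else if (kind == "angular") {
    delta <- 2 * pi / L
    edges <- -pi + delta * (seq_len(L) - 1)
  } else {
    delta <- pi / L
    edges <- delta * (seq_len(L) - 1)
  }
  colonymetrics:::new_colony_signal(
    tibble::tibble(bin = seq_len(L), left_edge = edges,
                   midpoint = edges + delta / 2, count = 0L,
                   expected = 1, value = values),
    kind,
    list(bin_count = L, bin_width = delta, n = n, rho = n / (pi * R^2),
         rho_A = n / (pi * (R^2 - R_A^2)), R = R, R_A = R_A)
  )
}

# Planted filament angles with a minimum circular gap, for recovery tests.
planted_angles <- function(n_f, min_gap = 0.15) {
  repeat {
    a <- sort(stats::runif(n_f, -pi, pi))
    gaps <- diff(c(a, a[1] + 2 * pi))
    if (all(gaps >= min_gap)) return(a)
  }
}
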