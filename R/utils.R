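# Internal helpers shared across modules.

# Clamp x into [lo, hi]; used before acos() where rounding can push a
# normalised dot product marginally outside [-1, 1].
clamp <- function(x, lo = -1, hi = 1) {
  pmin(pmax(x, lo), hi)
}

# Shortest angular distance on the circle, result in [0, pi].
circular_distance <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Assign values to 1..nbins equal-width bins over [lo, hi] with half-open
# bins [edge, edge + width) and a closed last bin, so x == hi lands in bin
# nbins rather than being dropped.
bin_index <- function(x, lo, hi, nbins) {
  idx <- floor((x - lo) / (hi - lo) * nbins) + 1L
  idx[idx > nbins & x <= hi] <- nbins
  idx
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
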