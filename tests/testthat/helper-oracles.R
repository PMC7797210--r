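# Independent brute-force oracles used to validate the fast implementations.
# Each oracle is deliberately naive and shares no code with the package path
# it checks.

# O(n^2) discrete Fourier transform with the same normalization and one-sided
# folding as regularity_power(): power_k = |X_k|^2 / n^2, interior bins
# doubled so the one-sided sum equals the population variance.
naive_dft_power <- function(x, pixel_size_um) {
  x <- x - mean(x)
  n <- length(x)
  ks <- 0:(n - 1)
  X <- vapply(ks, function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
  full <- Mod(X)^2 / n^2
  n_half <- floor(n / 2) + 1L
  power <- full[seq_len(n_half)]
  if (n %% 2 == 0) {
    power[2:(n_half - 1L)] <- 2 * power[2:(n_half - 1L)]
  } else if (n_half >= 2L) {
    power[2:n_half] <- 2 * power[2:n_half]
  }
  list(frequencies = (seq_len(n_half) - 1L) / (n * pixel_size_um),
       power = power)
}

# Exhaustive intra-class-variance minimizer: sweeps every midpoint between
# consecutive distinct intensities.
brute_force_otsu <- function(values) {
  v <- sort(unique(values))
  cands <- (v[-1] + v[-length(v)]) / 2
  icv <- vapply(cands, function(th) {
    lo <- values[values <= th]; hi <- values[values > th]
    w_lo <- length(lo) / length(values)
    v_lo <- if (length(lo) > 1) stats::var(lo) * (length(lo) - 1) / length(lo) else 0
    v_hi <- if (length(hi) > 1) stats::var(hi) * (length(hi) - 1) / length(hi) else 0
    w_lo * v_lo + (1 - w_lo) * v_hi
  }, numeric(1))
  cands[which.min(icv)]
}

# Width of a planar point set: the narrowest strip containing all points has
# a boundary through two of them, so the width is the minimum over point
# pairs of the directional extent along the pair's normal.
subset_strip_width <- function(x, y) {
  k <- length(x)
  if (k <= 2L) return(0)
  best <- Inf
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    proj <- (-x * dy + y * dx) / len
    best <- min(best, max(proj) - min(proj))
  }
  if (is.finite(best)) best else 0
}

# Exhaustive search over all subsets for the largest one fitting a strip of
# width 2 * tol (every member within tol of some line). Feasible for <= ~15
# points.
brute_force_max_aligned <- function(openings, lateral_tol_um) {
  k <- nrow(openings)
  if (k == 0L) return(0L)
  x <- openings$x; y <- openings$y
  for (m in k:2) {
    subsets <- utils::combn(k, m, simplify = FALSE)
    for (s in subsets) {
      if (subset_strip_width(x[s], y[s]) <= 2 * lateral_tol_um) {
        return(as.integer(m))
      }
    }
  }
  1L
}

# Per-sample level assignment by explicit comparison against the
# (k + 1/2) * i threshold grid, written without division/rounding.
threshold_grid_idealize <- function(x, unitary, max_level = 10L) {
  thresholds <- (seq_len(max_level) - 0.5) * unitary
  vapply(x, function(v) {
    lev <- 0L
    for (k in seq_len(max_level)) {
      crossed <- if (unitary > 0) v > thresholds[k] else v < thresholds[k]
      if (crossed) lev <- k else break
    }
    lev
  }, integer(1))
}

# Autocorrelation of a profile at integer pixel lags (direct O(n^2) form).
naive_autocorrelation <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  vapply(0:max_lag, function(L) {
    sum(x[1:(n - L)] * x[(1 + L):n]) / n
  }, numeric(1))
}
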