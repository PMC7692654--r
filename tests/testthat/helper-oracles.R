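# Independent oracles and fixture builders shared across test files.

# Brute-force SSE minimizer for the first-order rate: for each k on a
# fine grid the intercept is profiled out, and the k with the smallest
# residual sum of squares in log space wins. Deliberately ignorant of
# the closed-form OLS solution used by the implementation.
grid_search_rate <- function(times, values, k_max = 1, step = 1e-5) {
  y <- log(values / values[1])
  k_grid <- seq(0, k_max, by = step)
  resid <- outer(times - mean(times), k_grid) + (y - mean(y))
  sse <- colSums(resid^2)
  k_grid[which.min(sse)]
}

# Closed-form OLS slope/intercept from the normal equations, written
# out longhand as an oracle for the lm-based calibration fit.
normal_equations_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Noiseless exponential decay on the standard sampling grid.
exact_decay <- function(k, temperature = 120, c0 = 1,
                        times = c(0, 2, 5, 7, 10, 20, 30, 40)) {
  decay_series(temperature, times, c0 * exp(-k * times))
}

published_anthocyanin <- function() reference_kinetics("anthocyanin")
published_antioxidant <- function() reference_kinetics("antioxidant")
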