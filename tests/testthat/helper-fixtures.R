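# Shared fixture builders and independent oracles.

# Raster from an event list given as (channel, time_ms) 0-based pairs.
raster_from_events <- function(events, n_channels, duration_ms) {
  m <- matrix(0L, n_channels, duration_ms)
  if (length(events) > 0) {
    m[cbind(events[, 1] + 1L, events[, 2] + 1L)] <- 1L
  }
  mua_raster(m, seq_len(n_channels) - 1L, duration_ms)
}

# Independent grid-search oracle for the bounded power-law MLE: evaluates
# the log-likelihood on a 0.001-step grid by direct summation of the
# normalizer.
grid_mle_alpha <- function(data, x_min = min(data), x_max = max(data),
                           grid = seq(0.5, 5, by = 0.001)) {
  s_log <- sum(log(data))
  n <- length(data)
  ks <- seq(x_min, x_max)
  ll <- vapply(grid, function(a) -a * s_log - n * log(sum(ks^(-a))), 1)
  grid[which.max(ll)]
}

# Analytic magnitude response of an order-n Butterworth high-pass at
# frequency f for cut-off fc.
butter_hp_gain <- function(f, fc, order = 2) {
  1 / sqrt(1 + (fc / f)^(2 * order))
}

# RMS of the steady-state tail of a filtered trace (transient dropped).
steady_rms <- function(x, drop = 200) {
  x <- x[-seq_len(drop)]
  sqrt(mean(x^2))
}
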