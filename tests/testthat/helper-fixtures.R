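# shared fixture builders; everything generated in code, no stored data

# a small ternary-noise stimulus for quick STRF checks
quick_noise <- function(duration = 50, n_bars = 12, seed = 42) {
  make_ternary_noise(n_bars, 20, duration, seed = seed)
}

# a linear (rectifier off) LN neuron with known filter, for recovery tests
linear_neuron <- function(rf_sigma = 6.4, gain = 2, calcium_tau = 0.25,
                          rf_center = c(30, 27.5)) {
  neuron_model(rf_center = rf_center, rf_sigma = rf_sigma,
               temporal_filter = biphasic_filter(20),
               rectifier_threshold = -Inf, calcium_tau = calcium_tau,
               gain = gain)
}

# cosine similarity between two equally-shaped arrays
cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# independent reverse-correlation oracle: naive double loop over lags and
# bars (kept deliberately dumb; the implementation must match it)
naive_reverse_correlation <- function(r, s, n_lags) {
  r <- r - mean(r)
  T_ <- length(r)
  w <- matrix(0, n_lags, ncol(s))
  for (tau in 0:(n_lags - 1)) {
    for (b in seq_len(ncol(s))) {
      acc <- 0
      for (t in (tau + 1):T_) acc <- acc + r[t] * s[t - tau, b]
      w[tau + 1, b] <- acc / (T_ - tau)
    }
  }
  w
}

# independent Otsu oracle: exhaustive search over all cut points of the
# 256-bin histogram (values represented by their bin mid), maximizing
# between-class variance computed directly per cut; first (lowest) cut
# wins ties
exhaustive_otsu <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  v_mid <- mids[bin]
  best_var <- -Inf; best_edge <- NA
  for (k in 1:(n_bins - 1)) {
    lo <- v_mid[bin <= k]; hi <- v_mid[bin > k]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) * (mean(lo) - mean(v_mid))^2 +
            length(hi) * (mean(hi) - mean(v_mid))^2) / length(v_mid)
    if (!is.finite(best_var) || v > best_var + 1e-9 * max(1, abs(best_var))) {
      best_var <- v; best_edge <- edges[k + 1]
    }
  }
  best_edge
}

# direct complex-summation oracle for the circular tuning vector
direct_ldir <- function(R, angles_deg) {
  R <- pmax(R, 0)
  z <- 0
  for (k in seq_along(R)) z <- z + R[k] * exp(1i * angles_deg[k] * pi / 180)
  z / sum(R)
}
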