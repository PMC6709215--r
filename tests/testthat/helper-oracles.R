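# Independent brute-force oracles and small fixture builders.

# Direct double-sum lagged cross-correlation (the definition, no FFT):
# tau >= 0: sum_t x(t+tau) y(t); tau < 0: sum_t x(t) y(t+|tau|).
direct_xcorr <- function(x, y, tau) {
  T <- length(x)
  if (tau >= 0) sum(x[(1 + tau):T] * y[1:(T - tau)])
  else sum(x[1:(T + tau)] * y[(1 - tau):T])
}

direct_rcoeff <- function(x, y, tau) {
  direct_xcorr(x, y, tau) / sqrt(sum(x^2) * sum(y^2))
}

# Hand-built correlogram object for extrema tests.
toy_correlogram <- function(max_lag, spikes = list()) {
  lags <- -max_lag:max_lag
  values <- numeric(length(lags))
  for (s in spikes) values[lags == s[1]] <- s[2]
  structure(list(lags = lags, values = values), class = "correlogram")
}

# Two-channel segment where channel 2 is a noisy delayed copy of channel 1.
delayed_pair_segment <- function(fs, delay, seed, sd_noise = 0.3,
                                 seg_len_s = 1) {
  L <- round(seg_len_s * fs)
  set.seed(seed)
  base <- rnorm(L + delay)
  rbind(base[(delay + 1):(delay + L)],
        0.9 * base[1:L] + rnorm(L, sd = sd_noise))
}

# Small recording wrapper; layout is a placeholder (preprocessing ignores it).
toy_recording <- function(data, fs, annotations = NULL) {
  n <- nrow(data)
  lay <- make_layout(1, n + n %% 2)
  ictonet:::new_recording(data, fs, lay, annotations)
}

# Classical MDS by explicit double-centering (independent of cmdscale).
oracle_mds <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10)[seq_len(k)]
  X <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  emb <- as.matrix(dist(X))
  low <- lower.tri(D)
  cor(D[low], emb[low])
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (small n only).
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- mean(us)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Infer one recording's ABS connectivity with reduced surrogate count
# (shared by cohort-level recovery tests).
quick_abs_connectivity <- function(rec, seed, n_surrogate_sets = 10,
                                   band_high = 90) {
  rec <- rereference_average(rec)
  rec <- filter_recording(rec, notch_freqs = 50, band = c(1, band_high))
  ss <- select_segments(rec)
  recording_connectivity_all(ss, n_surrogate_sets = n_surrogate_sets,
                             seed = seed)$abs
}
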