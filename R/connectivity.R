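#' Lag mask for cross-correlogram extrema
#'
#' Connectivity inference ignores very short lags (volume conduction: common
#' sources appear as near-zero-lag correlation) and very long lags. Defaults
#' correspond to 2 ms and 250 ms at a 4 kHz sampling rate: 8 and 1000
#' samples.
#'
#' @param min_lag Smallest retained |lag| in samples (> 0).
#' @param max_lag Largest retained |lag| in samples.
#' @return Object of class `lag_mask`.
#' @seealso [lag_mask_for_fs()] for rate-aware defaults.
#' @export
lag_mask <- function(min_lag = 8, max_lag = 1000) {
  stopifnot(min_lag > 0, min_lag < max_lag)
  structure(list(min_lag = as.integer(min_lag),
                 max_lag = as.integer(max_lag)), class = "lag_mask")
}

#' @describeIn lag_mask The same 2 ms / 250 ms bounds expressed in samples
#'   at an arbitrary sampling rate: `min_lag = ceiling(0.002 * fs)`,
#'   `max_lag = round(0.25 * fs)`.
#' @param fs Sampling rate in Hz.
#' @export
lag_mask_for_fs <- function(fs) {
  lag_mask(ceiling(0.002 * fs), round(0.25 * fs))
}

# Full linear cross-correlation r(tau) = sum_t x(t+tau) y(t) via FFT,
# tau = -(T-1) .. (T-1). No normalization, no demeaning.
raw_xcorr <- function(x, y) {
  T <- length(x)
  nfft <- stats::nextn(2L * T - 1L, 2)
  X <- fft(c(x, numeric(nfft - T)))
  Y <- fft(c(y, numeric(nfft - T)))
  cc <- Re(fft(X * Conj(Y), inverse = TRUE)) / nfft
  # cc[1 + s] = r(s) for s >= 0; cc[nfft + 1 + s] = r(s) for s < 0
  tau <- -(T - 1):(T - 1)
  vals <- numeric(length(tau))
  vals[tau >= 0] <- cc[1 + tau[tau >= 0]]
  vals[tau < 0] <- cc[nfft + 1 + tau[tau < 0]]
  list(lags = tau, values = vals)
}

#' Normalized cross-correlogram of two equal-length series
#'
#' Computes the lagged cross-correlation `r(x, y)(tau)` (sum of products at
#' relative shift `tau`, without mean subtraction) normalized by
#' `sqrt(r(x,x)(0) * r(y,y)(0))`, so that the autocorrelation of any series
#' at lag zero equals 1 and all values lie in [-1, 1]. Negative lags mean
#' that `x` temporally leads `y`.
#'
#' @param x,y Numeric vectors of equal length `T >= 2` with nonzero
#'   variance.
#' @param max_lag Largest |lag| to return (default `T - 1`).
#' @param demean If `TRUE`, subtract each series' mean first (off by
#'   default: the estimator is defined on the raw products).
#' @return Object of class `correlogram`: list with `lags` (samples) and
#'   `values` (in [-1, 1]).
#' @examples
#' x <- sin(seq(0, 10, length.out = 200))
#' cg <- cross_correlogram(x, x)
#' cg$values[cg$lags == 0]  # 1
#' @export
cross_correlogram <- function(x, y, max_lag = length(x) - 1L,
                              demean = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: cross-correlogram undefined (zero norm)")
  if (demean) { x <- x - mean(x); y <- y - mean(y) }
  cc <- raw_xcorr(x, y)
  norm <- sqrt(sum(x^2) * sum(y^2))
  keep <- abs(cc$lags) <= max_lag
  structure(list(lags = cc$lags[keep], values = cc$values[keep] / norm),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  pk <- which.max(abs(x$values))
  cat("<correlogram> lags ", min(x$lags), "..", max(x$lags),
      "; |peak| ", round(abs(x$values[pk]), 3), " at lag ", x$lags[pk],
      "\n", sep = "")
  invisible(x)
}

# Extrema of one correlogram half. Returns c(abs, max, min) values and lags.
half_extrema <- function(vals, lags) {
  mx <- 0; mx_lag <- NA_integer_
  mn <- 0; mn_lag <- NA_integer_
  if (any(vals > 0)) { i <- which.max(vals); mx <- vals[i]; mx_lag <- lags[i] }
  if (any(vals < 0)) { i <- which.min(vals); mn <- -vals[i]; mn_lag <- lags[i] }
  ab <- max(mx, mn)
  ab_lag <- if (mx >= mn) mx_lag else mn_lag
  list(abs = ab, max = mx, min = mn,
       abs_lag = ab_lag, max_lag = mx_lag, min_lag = mn_lag)
}

#' Masked lag extrema of a cross-correlogram, by direction
#'
#' Splits the correlogram of a channel pair (x_i, x_j) into its negative-lag
#' half (x_i leads x_j: the forward direction i -> j) and positive-lag half
#' (reverse direction), drops lags outside the mask, and returns for each
#' half the three connection-strength readings: `max` (largest positive
#' value, 0 if none), `min` (magnitude of the most negative value, 0 if
#' none) and `abs = max(max, min)`.
#'
#' @param cg A [cross_correlogram()].
#' @param mask A [lag_mask()].
#' @return List with elements `fwd` and `rev`, each holding `abs`, `max`,
#'   `min` and the lags at which they occur.
#' @export
lag_extrema <- function(cg, mask) {
  stopifnot(inherits(cg, "correlogram"), inherits(mask, "lag_mask"))
  in_mask <- abs(cg$lags) >= mask$min_lag & abs(cg$lags) <= mask$max_lag
  if (!any(in_mask)) stop("lag mask excludes every available lag")
  fwd <- in_mask & cg$lags < 0
  rev <- in_mask & cg$lags > 0
  list(fwd = half_extrema(cg$values[fwd], cg$lags[fwd]),
       rev = half_extrema(cg$values[rev], cg$lags[rev]))
}

#' Iterative amplitude adjusted Fourier transform (IAAFT) surrogate
#'
#' Generates a randomized copy of `x` whose amplitude distribution equals
#' the original's exactly (identical sorted values) and whose power spectrum
#' approximates the original's. Each iteration enforces the original
#' spectrum magnitude (keeping current phases) and then rank-remaps the
#' result onto the original amplitudes; the amplitude step comes last, so
#' the value-distribution match is exact.
#'
#' @param x Numeric vector, length >= 4. A constant series is returned
#'   unchanged.
#' @param n_iterations Number of spectrum/amplitude adjustment rounds
#'   (default 10).
#' @param seed Optional seed for the initial random shuffle.
#' @return Numeric surrogate of the same length.
#' @export
iaaft_surrogate <- function(x, n_iterations = 10, seed = NULL) {
  stopifnot(length(x) >= 4, all(is.finite(x)))
  if (stats::sd(x) == 0) return(x)
  n <- length(x)
  amp <- sort(x)
  target_mag <- Mod(fft(x))
  s <- if (is.null(seed)) sample(x) else with_seed(seed, sample(x))
  for (it in seq_len(n_iterations)) {
    ph <- Arg(fft(s))
    s2 <- Re(fft(target_mag * exp(1i * ph), inverse = TRUE)) / n
    s <- amp[rank(s2, ties.method = "first")]
  }
  s
}

#' Windowing and multiple-testing plan for segment connectivity
#'
#' Lays out the analysis plan used by [segment_connectivity()]: sliding
#' windows over a segment, the number of element-wise significance tests
#' (one per ordered channel pair, Bonferroni family size `n * (n - 1)`), the
#' surrogate window count, and the lag mask. With the defaults on a 1 s
#' segment, `n_windows = 21` windows of 500 ms imply a 25 ms stride.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param seg_len_s Segment length in seconds (default 1).
#' @param win_len_s Window length in seconds (default 0.5).
#' @param n_windows Number of sliding windows per segment (default 21).
#' @param n_surrogate_sets Surrogate ensembles per segment (default 100).
#' @param mask Optional [lag_mask()]; default [lag_mask_for_fs()] at `fs`.
#' @return Object of class `connectivity_plan`: window start indices and
#'   length, `n_windows`, `n_comparisons`, `n_surrogate_windows`, `mask`.
#' @export
connectivity_plan <- function(n_channels, fs, seg_len_s = 1,
                              win_len_s = 0.5, n_windows = 21,
                              n_surrogate_sets = 100, mask = NULL) {
  stopifnot(n_channels >= 2, n_windows >= 2)
  L <- round(seg_len_s * fs)
  win <- round(win_len_s * fs)
  if (win < 2 || win >= L)
    stop("window length not representable within the segment")
  stride <- (L - win) / (n_windows - 1)
  if (stride <= 0 || stride != round(stride))
    stop("window layout not representable in samples: (L - win) must be ",
         "divisible by n_windows - 1")
  if (is.null(mask)) mask <- lag_mask_for_fs(fs)
  if (mask$max_lag >= win)
    stop("lag mask exceeds the window length")
  structure(list(
    window_starts = 1L + (seq_len(n_windows) - 1L) * as.integer(stride),
    window_len = as.integer(win), segment_len = as.integer(L),
    n_windows = as.integer(n_windows),
    n_comparisons = as.integer(n_channels * (n_channels - 1)),
    n_surrogate_sets = as.integer(n_surrogate_sets),
    n_surrogate_windows = as.integer(n_surrogate_sets * n_windows),
    mask = mask, fs = fs
  ), class = "connectivity_plan")
}

# Per-window extrema for all ordered channel pairs at once. W is channels x
# win. Returns list of three n x n matrices (abs, max, min); element [i, j]
# is the forward (i leads j, negative-lag) reading for i -> j.
window_pair_extrema <- function(W, mask, demean = FALSE) {
  n <- nrow(W); T <- ncol(W)
  if (demean) W <- W - rowMeans(W)
  nfft <- stats::nextn(2L * T - 1L, 2)
  pad <- matrix(0, nfft, n)
  pad[seq_len(T), ] <- t(W)
  Xf <- stats::mvfft(pad)
  norms <- rowSums(W^2)
  u <- mask$min_lag:min(mask$max_lag, T - 1L)
  A <- matrix(0, n, n); M <- matrix(0, n, n); Mn <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    nrm <- sqrt(norms[i] * norms[j])
    if (nrm == 0) next
    cc <- Re(fft(Xf[, i] * Conj(Xf[, j]), inverse = TRUE)) / nfft
    fwd <- cc[nfft + 1L - u] / nrm   # tau = -u: i leads j
    rev <- cc[1L + u] / nrm          # tau = +u: j leads i
    ef <- half_extrema(fwd, -u); er <- half_extrema(rev, u)
    A[i, j] <- ef$abs; M[i, j] <- ef$max; Mn[i, j] <- ef$min
    A[j, i] <- er$abs; M[j, i] <- er$max; Mn[j, i] <- er$min
  }
  list(abs = A, max = M, min = Mn)
}

# Rank-sum p-value robust to the all-tied degenerate case.
ranksum_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
}

new_connectivity_matrix <- function(weights, method, normalized,
                                    n_segments_used = NA_integer_) {
  diag(weights) <- 0
  structure(list(weights = weights, method = toupper(method),
                 normalized = normalized,
                 n_segments_used = n_segments_used),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> C^", x$method, ", ", nrow(x$weights), " x ",
      ncol(x$weights), ", ", sum(x$weights != 0), " nonzero, ",
      if (isTRUE(x$normalized)) "sum-normalized" else "unnormalized",
      if (!is.na(x$n_segments_used))
        paste0(", ", x$n_segments_used, " segment(s)") else "",
      "\n", sep = "")
  invisible(x)
}

# Core segment-level estimator shared by the ABS/MAX/MIN variants: one
# surrogate ensemble serves all three.
segment_conn_core <- function(segment, fs, plan, alpha = 0.05, seed,
                              demean = FALSE) {
  n <- nrow(segment)
  stopifnot(ncol(segment) == plan$segment_len)
  methods <- c("abs", "max", "min")
  nw <- plan$n_windows
  win_of <- function(mat, a) mat[, a:(a + plan$window_len - 1L), drop = FALSE]

  data_vals <- lapply(methods, function(m) array(0, c(n, n, nw)))
  names(data_vals) <- methods
  for (w in seq_len(nw)) {
    ex <- window_pair_extrema(win_of(segment, plan$window_starts[w]),
                              plan$mask, demean)
    for (m in methods) data_vals[[m]][, , w] <- ex[[m]]
  }

  ns <- plan$n_surrogate_sets
  surr_vals <- lapply(methods, function(m) array(0, c(n, n, ns * nw)))
  names(surr_vals) <- methods
  ch_seeds <- matrix(derive_seeds(seed, n * ns, salt = 17), nrow = n)
  for (s in seq_len(ns)) {
    surr <- segment
    for (i in seq_len(n))
      surr[i, ] <- iaaft_surrogate(segment[i, ], seed = ch_seeds[i, s])
    for (w in seq_len(nw)) {
      ex <- window_pair_extrema(win_of(surr, plan$window_starts[w]),
                                plan$mask, demean)
      slot <- (s - 1L) * nw + w
      for (m in methods) surr_vals[[m]][, , slot] <- ex[[m]]
    }
  }

  out <- lapply(methods, function(m) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- data_vals[[m]][i, j, ]
      s <- surr_vals[[m]][i, j, ]
      p <- ranksum_p(d, s)
      if (min(1, p * plan$n_comparisons) >= alpha) next  # s_ij = 0
      med_d <- stats::median(d); med_s <- stats::median(s)
      if (med_s >= 1) next
      W[i, j] <- max(0, (med_d - med_s) / (1 - med_s))
    }
    cm <- new_connectivity_matrix(W, m, normalized = FALSE, 1L)
    attr(cm, "plan") <- plan
    cm
  })
  names(out) <- methods
  out
}

#' Directed connectivity of one 1 s segment (all three variants)
#'
#' Estimates the surrogate-corrected directed connectivity matrix of a
#' single segment. The segment is cut into `n_windows` sliding windows; per
#' window and ordered channel pair the masked cross-correlogram extremum is
#' taken (the ABS / MAX / MIN reading). Per element, a two-sided Wilcoxon
#' rank-sum test compares the data-window values against the values from
#' `n_surrogate_sets` univariate IAAFT surrogate ensembles (windowed
#' identically), Bonferroni-corrected over the `n * (n - 1)` elements.
#' Significant elements get the normalized excess-over-surrogate weight
#' `(median_data - median_surr) / (1 - median_surr)` (clamped at 0);
#' non-significant elements are 0.
#'
#' `segment_connectivity()` returns the matrix for one `method`;
#' `segment_connectivity_all()` returns all three variants computed from the
#' same surrogate ensemble.
#'
#' @param segment channels x L numeric matrix (L = `seg_len_s * fs`).
#' @param fs Sampling rate in Hz.
#' @param method `"abs"`, `"max"` or `"min"`.
#' @param mask Optional [lag_mask()] (default from `fs`).
#' @param n_windows,win_len_s,n_surrogate_sets See [connectivity_plan()].
#' @param alpha Familywise error level of the element-wise test (default
#'   0.05).
#' @param seed Integer seed driving the surrogate ensemble.
#' @param demean Subtract window means before correlating (default FALSE).
#' @return A `connectivity_matrix` (unnormalized segment-level weights), or
#'   for `segment_connectivity_all()` a named list of the three variants.
#' @export
segment_connectivity <- function(segment, fs, method = c("abs", "max", "min"),
                                 mask = NULL, n_windows = 21,
                                 win_len_s = 0.5, n_surrogate_sets = 100,
                                 alpha = 0.05, seed, demean = FALSE) {
  method <- match.arg(method)
  segment_connectivity_all(segment, fs, mask, n_windows, win_len_s,
                           n_surrogate_sets, alpha, seed, demean)[[method]]
}

#' @rdname segment_connectivity
#' @export
segment_connectivity_all <- function(segment, fs, mask = NULL,
                                     n_windows = 21, win_len_s = 0.5,
                                     n_surrogate_sets = 100, alpha = 0.05,
                                     seed, demean = FALSE) {
  stopifnot(is.matrix(segment), nrow(segment) >= 2)
  plan <- connectivity_plan(nrow(segment), fs,
                            seg_len_s = ncol(segment) / fs,
                            win_len_s = win_len_s, n_windows = n_windows,
                            n_surrogate_sets = n_surrogate_sets, mask = mask)
  segment_conn_core(segment, fs, plan, alpha, seed, demean)
}

#' Recording-level connectivity: segment average, sum-normalized
#'
#' Runs [segment_connectivity()] on every segment of a [select_segments()]
#' result, averages the matrices elementwise, and normalizes the average by
#' the sum of its elements (skipped, with `normalized = FALSE`, if the
#' average is all zero).
#'
#' @param segs A `segment_set`.
#' @param method `"abs"`, `"max"` or `"min"`.
#' @inheritParams segment_connectivity
#' @return A normalized `connectivity_matrix` with `n_segments_used` set.
#' @export
recording_connectivity <- function(segs, method = c("abs", "max", "min"),
                                   mask = NULL, n_windows = 21,
                                   win_len_s = 0.5, n_surrogate_sets = 100,
                                   alpha = 0.05, seed, demean = FALSE) {
  method <- match.arg(method)
  recording_connectivity_all(segs, mask, n_windows, win_len_s,
                             n_surrogate_sets, alpha, seed, demean)[[method]]
}

#' @rdname recording_connectivity
#' @export
recording_connectivity_all <- function(segs, mask = NULL, n_windows = 21,
                                       win_len_s = 0.5,
                                       n_surrogate_sets = 100, alpha = 0.05,
                                       seed, demean = FALSE) {
  stopifnot(inherits(segs, "segment_set"))
  if (segs$n_segments < 1) stop("empty segment set")
  seeds <- derive_seeds(seed, segs$n_segments, salt = 29)
  per_seg <- lapply(seq_len(segs$n_segments), function(k)
    segment_connectivity_all(segs$segments[[k]], segs$fs, mask, n_windows,
                             win_len_s, n_surrogate_sets, alpha,
                             seed = seeds[k], demean = demean))
  lapply(stats::setNames(nm = c("abs", "max", "min")), function(m) {
    W <- Reduce(`+`, lapply(per_seg, function(x) x[[m]]$weights)) /
      segs$n_segments
    tot <- sum(W)
    normalized <- tot > 0
    if (normalized) W <- W / tot
    cm <- new_connectivity_matrix(W, m, normalized, segs$n_segments)
    attr(cm, "n_nonzero") <- sum(W != 0)
    cm
  })
}

#' Quality-control exclusion of recordings
#'
#' A recording is kept only if it yielded at least `min_segments` background
#' segments and its averaged connectivity matrix has at least `min_nonzero`
#' nonzero elements.
#'
#' @param stats data.frame with columns `n_segments` and `n_nonzero` (one
#'   row per recording).
#' @param min_segments,min_nonzero Inclusion thresholds.
#' @return Logical keep-flag vector.
#' @export
qc_exclusion <- function(stats, min_segments = 17, min_nonzero = 50) {
  stopifnot(min_segments >= 0, min_nonzero >= 0,
            all(c("n_segments", "n_nonzero") %in% names(stats)))
  stats$n_segments >= min_segments & stats$n_nonzero >= min_nonzero
}
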