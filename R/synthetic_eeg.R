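#' Mirror-symmetric electrode grid layout
#'
#' Builds a rectangular epicranial-style electrode grid with an even number
#' of columns split into left and right hemispheres. Each electrode is
#' paired with its mirror image across the midline (column `c` with column
#' `n_cols - 1 - c` in the same row), giving the contralateral pairing used
#' by [contralateral_top_fraction()] and by the symmetry structure of
#' synthetic cohorts.
#'
#' @param n_rows Number of anterior-posterior rows.
#' @param n_cols Number of left-right columns; must be even so each channel
#'   has a contralateral mirror.
#' @return An object of class `electrode_layout`: a list with `n_channels`,
#'   `positions` (n x 2 matrix, columns `x` = left-right, `y` =
#'   anterior-posterior), `contralateral_pair` (integer vector, an
#'   involution without fixed points), and `hemisphere` (`"left"` /
#'   `"right"` per channel).
#' @examples
#' lay <- make_layout(5, 6)
#' all(lay$contralateral_pair[lay$contralateral_pair] == seq_len(30))
#' @export
make_layout <- function(n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 2)
  if (n_cols %% 2 != 0)
    stop("n_cols must be even: mirror pairing needs equal left/right halves")
  n <- n_rows * n_cols
  # channel index = (row - 1) * n_cols + col, row-major
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  pair <- (row - 1L) * n_cols + (n_cols + 1L - col)
  structure(list(
    n_channels = n,
    positions = cbind(x = col, y = row),
    contralateral_pair = as.integer(pair),
    hemisphere = ifelse(col <= n_cols / 2, "left", "right")
  ), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> ", x$n_channels, " channels (",
      max(x$positions[, "y"]), " x ", max(x$positions[, "x"]),
      " grid, mirror-paired)\n", sep = "")
  invisible(x)
}

#' Ground-truth latent-source network for synthetic EEG
#'
#' Describes how latent band-limited sources project onto channels: a signed
#' gain matrix and a nonnegative per-channel/source delay (in samples). A
#' channel receiving a source at a larger delay than another channel lags it,
#' which plants a directed, lagged coupling that downstream connectivity
#' inference should recover.
#'
#' @param mixing channels x sources signed gain matrix.
#' @param lags channels x sources matrix of delays in samples (>= 0).
#' @param sources data.frame with one row per source: `low`, `high` (band
#'   edges in Hz) and `sd` (source amplitude scale).
#' @param noise_sd Per-channel sensor noise standard deviation (scalar or
#'   vector of length channels).
#' @return Object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(mixing, lags, sources, noise_sd = 0.5) {
  mixing <- as.matrix(mixing); lags <- as.matrix(lags)
  stopifnot(identical(dim(mixing), dim(lags)),
            nrow(sources) == ncol(mixing),
            all(c("low", "high", "sd") %in% names(sources)))
  if (any(lags < 0)) stop("all lags must be >= 0")
  structure(list(mixing = mixing, lags = lags, sources = sources,
                 noise_sd = rep_len(noise_sd, nrow(mixing))),
            class = "ground_truth_network")
}

#' Effective directed channel-coupling matrix of a ground truth
#'
#' Summarizes the planted structure as a directed channel x channel matrix:
#' entry (i, j) accumulates |gain_i * gain_j| over sources that reach channel
#' i strictly before channel j (so i temporally leads j). Used to check
#' planted symmetry and planted degree imbalance; it is not an estimate.
#'
#' @param truth A [ground_truth_network()].
#' @return channels x channels nonnegative matrix with zero diagonal.
#' @export
truth_coupling <- function(truth) {
  n <- nrow(truth$mixing)
  G <- matrix(0, n, n)
  for (k in seq_len(ncol(truth$mixing))) {
    m <- truth$mixing[, k]
    lg <- truth$lags[, k]
    on <- which(m != 0)
    for (i in on) for (j in on) {
      if (lg[i] < lg[j]) G[i, j] <- G[i, j] + abs(m[i] * m[j])
    }
  }
  diag(G) <- 0
  G
}

# Order-2 Butterworth band-pass filtered white noise, unit-sd rescaled.
band_limited_noise <- function(n, fs, low, high, sd = 1) {
  x <- rnorm(n)
  ny <- fs / 2
  if (high >= ny) high <- 0.99 * ny
  bf <- signal::butter(2, c(low, high) / ny, type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- stats::sd(y)
  if (s > 0) y <- y / s * sd
  y
}

#' Generate a multichannel recording from a ground-truth network
#'
#' Each channel is a lagged, signed mixture of band-limited (1-150 Hz by
#' default, set per source) Gaussian sources plus white sensor noise:
#' `x_i(t) = sum_k mixing[i,k] * s_k(t - lags[i,k]) + noise`. Deterministic
#' given `seed`.
#'
#' @param truth A [ground_truth_network()].
#' @param layout An [make_layout()] layout with `n_channels == nrow(mixing)`.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (default 4000).
#' @param seed Integer seed.
#' @param annotations Optional data.frame (`event_type`, `onset_sample`)
#'   attached to the recording.
#' @return Object of class `eeg_recording`: list with `data` (channels x
#'   samples), `fs`, `layout`, `annotations`, and the generating `truth`.
#' @export
generate_recording <- function(truth, layout, duration_s, fs = 4000, seed,
                               annotations = NULL) {
  n_samp <- round(duration_s * fs)
  max_lag <- max(truth$lags)
  if (n_samp <= max_lag)
    stop("recording shorter than the longest planted lag")
  n_ch <- nrow(truth$mixing)
  stopifnot(layout$n_channels == n_ch)
  data <- with_seed(seed, {
    src <- vapply(seq_len(nrow(truth$sources)), function(k)
      band_limited_noise(n_samp + max_lag, fs,
                         truth$sources$low[k], truth$sources$high[k],
                         truth$sources$sd[k]),
      numeric(n_samp + max_lag))
    out <- matrix(0, n_ch, n_samp)
    for (i in seq_len(n_ch)) {
      for (k in seq_len(ncol(truth$mixing))) {
        g <- truth$mixing[i, k]
        if (g == 0) next
        d <- truth$lags[i, k]
        # s_k(t - d): read the source stream shifted by d
        out[i, ] <- out[i, ] + g * src[max_lag - d + seq_len(n_samp), k]
      }
      out[i, ] <- out[i, ] + rnorm(n_samp, sd = truth$noise_sd[i])
    }
    out
  })
  new_recording(data, fs, layout, annotations, truth)
}

new_recording <- function(data, fs, layout, annotations = NULL, truth = NULL) {
  stopifnot(is.matrix(data), all(is.finite(data)), fs > 0)
  if (is.null(annotations))
    annotations <- data.frame(event_type = character(), onset_sample = integer())
  stopifnot(all(annotations$onset_sample >= 0),
            all(annotations$onset_sample < ncol(data)))
  structure(list(data = data, fs = fs, layout = layout,
                 annotations = annotations, truth = truth),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz; ", nrow(x$annotations),
      " annotated event(s)\n", sep = "")
  invisible(x)
}

# Add a biphasic high-amplitude transient (generalized-spike stand-in) to all
# channels at each onset and record the annotation. Width 30-50 ms.
add_gs_events <- function(rec, onsets, width_s = 0.04, amplitude = 8) {
  w <- max(4L, round(width_s * rec$fs))
  half <- w %/% 2
  shape <- c(sin(seq(0, pi, length.out = half)),
             -sin(seq(0, pi, length.out = w - half)))
  scale <- amplitude * stats::median(apply(rec$data, 1, stats::sd))
  for (o in onsets) {
    idx <- o + seq_len(w)
    idx <- idx[idx <= ncol(rec$data)]
    rec$data[, idx] <- rec$data[, idx] +
      matrix(scale * shape[seq_along(idx)], nrow(rec$data), length(idx),
             byrow = TRUE)
  }
  rec$annotations <- rbind(rec$annotations,
                           data.frame(event_type = "GS",
                                      onset_sample = as.integer(onsets)))
  rec
}

# Build the stage-specific ground truth for one subject. Sources come in
# mirror pairs so that day0/sham mixing commutes with the contralateral
# permutation; day7/day28 break symmetry by boosting outgoing couplings from
# the left posterior node set and shrinking inter-hemispheric gains.
cohort_truth <- function(stage, layout, fs, gain_jitter) {
  n <- layout$n_channels
  pair <- layout$contralateral_pair
  left <- which(layout$hemisphere == "left")
  d_contra <- max(2L, round(0.015 * fs))   # 15 ms inter-hemispheric lag
  d_ipsi <- max(1L, round(0.010 * fs))     # 10 ms within-hemisphere lag
  g_contra <- 0.8
  g_ipsi <- 0.5
  # stage-dependent modifiers
  boost <- switch(stage, day0 = 1, sham = 1, day7 = 1.75, day28 = 2.5)
  shrink <- switch(stage, day0 = 1, sham = 1, day7 = 0.6, day28 = 0.35)
  # left posterior node set: left-hemisphere channels in the last row
  post_row <- max(layout$positions[, "y"])
  lp <- left[layout$positions[left, "y"] == post_row]

  n_src <- 2L * length(left) + 1L
  mixing <- matrix(0, n, n_src)
  lags <- matrix(0L, n, n_src)
  bands <- data.frame(low = rep(1, n_src), high = rep(150, n_src),
                      sd = rep(1, n_src))
  # next ipsilateral channel: cyclic successor within the left hemisphere in
  # index order; on the right, the mirror image of the left successor, so the
  # construction commutes with the contralateral permutation
  next_left <- function(ch) left[(match(ch, left) %% length(left)) + 1L]
  next_ipsi <- function(ch) {
    if (layout$hemisphere[ch] == "left") next_left(ch)
    else pair[next_left(pair[ch])]
  }
  k <- 0L
  for (idx in seq_along(left)) {
    l <- left[idx]; r <- pair[l]
    sgn <- if (idx %% 2 == 0) -1 else 1  # alternate sign: plant anticorrelations
    jit <- gain_jitter[idx]
    for (leader in c(l, r)) {
      k <- k + 1L
      follower <- pair[leader]
      b <- if (leader %in% lp) boost else 1
      mixing[leader, k] <- 1 * jit
      mixing[follower, k] <- sgn * g_contra * shrink * b * jit
      lags[follower, k] <- d_contra
      nx <- next_ipsi(leader)
      mixing[nx, k] <- mixing[nx, k] + g_ipsi * b * jit
      lags[nx, k] <- d_ipsi
    }
  }
  # shared zero-lag background (volume-conduction stand-in)
  k <- k + 1L
  mixing[, k] <- 0.3
  ground_truth_network(mixing, lags, bands, noise_sd = 0.5)
}

#' Generate a synthetic cohort of recordings for one study stage
#'
#' Stages emulate a longitudinal design around a focal left-hippocampal
#' insult: `day0` and `sham` cohorts have mirror-symmetric planted coupling
#' (the ground-truth coupling matrix commutes with the contralateral
#' permutation), while `day7` and `day28` cohorts break that symmetry by
#' strengthening outgoing couplings from a left posterior node set and
#' weakening inter-hemispheric couplings. `day7`/`day28` recordings carry
#' planted generalized-spike (GS) annotations; all stages carry occasional
#' artifact annotations.
#'
#' @param stage One of `"day0"`, `"day7"`, `"day28"`, `"sham"`.
#' @param n_subjects Number of recordings; defaults mirror the study design
#'   (11 at day0/day28, 7 at day7, 4 sham).
#' @param seed Integer seed; subjects get derived sub-seeds.
#' @param layout Electrode layout (default 5 x 6 grid, 30 channels).
#' @param fs Sampling rate in Hz.
#' @param duration_s Per-recording duration in seconds.
#' @return List of `eeg_recording` objects; each carries its generating
#'   ground truth in `$truth`.
#' @export
generate_cohort <- function(stage, n_subjects = NULL, seed,
                            layout = make_layout(5, 6), fs = 4000,
                            duration_s = 60) {
  stages <- c("day0", "day7", "day28", "sham")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of ",
         paste(stages, collapse = ", "))
  if (is.null(n_subjects))
    n_subjects <- c(day0 = 11, day7 = 7, day28 = 11, sham = 4)[[stage]]
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(seed, n_subjects, salt = match(stage, stages))
  lapply(seq_len(n_subjects), function(s) {
    n_left <- sum(layout$hemisphere == "left")
    jit <- with_seed(seeds[s], runif(n_left, 0.8, 1.2))
    truth <- cohort_truth(stage, layout, fs, jit)
    rec <- generate_recording(truth, layout, duration_s, fs,
                              seed = seeds[s] + 1)
    n_samp <- ncol(rec$data)
    if (stage %in% c("day7", "day28")) {
      onsets <- with_seed(seeds[s] + 2, {
        lo <- min(2.5 * fs, floor(n_samp / 2))
        hi <- max(lo, n_samp - fs)
        base <- seq(lo, hi, by = 5 * fs)
        pmin(n_samp - 1, pmax(0, round(base + runif(length(base), -fs, fs))))
      })
      rec <- add_gs_events(rec, onsets)
    }
    if (duration_s >= 30) {
      art <- seq(15 * fs, n_samp - 1, by = 30 * fs)
      rec$annotations <- rbind(rec$annotations,
                               data.frame(event_type = "artifact",
                                          onset_sample = as.integer(art)))
    }
    rec
  })
}
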