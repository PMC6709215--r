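#' Re-reference a recording to the channel average
#'
#' Subtracts, at every sample, the mean across channels. After
#' re-referencing the across-channel mean is identically zero, and the
#' operation is idempotent.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("average re-referencing needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Notch and band-pass filter a recording (zero-phase Butterworth)
#'
#' Applies narrow band-stop (notch) filters at the given power-line
#' frequencies, then an order-`order` Butterworth band-pass, all zero-phase
#' (forward-reverse filtering), channel by channel. Defaults: notch at 50 Hz
#' and its 100/150 Hz harmonics, pass band 1-150 Hz, order 2.
#'
#' @param rec An `eeg_recording`.
#' @param notch_freqs Frequencies (Hz) to notch out; `NULL` to skip.
#' @param band Length-2 numeric `(low, high)` pass band in Hz.
#' @param order Butterworth order of the band-pass (each notch is order 2).
#' @param notch_width Full stop-band width of each notch in Hz.
#' @return The filtered recording.
#' @export
filter_recording <- function(rec, notch_freqs = c(50, 100, 150),
                             band = c(1, 150), order = 2, notch_width = 2) {
  stopifnot(inherits(rec, "eeg_recording"), length(band) == 2)
  ny <- rec$fs / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < ny))
    stop("pass band must satisfy 0 < low < high < fs/2")
  if (length(notch_freqs) && any(notch_freqs >= ny))
    stop("notch frequencies must be below the Nyquist frequency")
  filts <- lapply(notch_freqs, function(f0)
    signal::butter(2, c(f0 - notch_width / 2, f0 + notch_width / 2) / ny,
                   type = "stop"))
  filts <- c(filts, list(signal::butter(order, band / ny, type = "pass")))
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    for (bf in filts) x <- signal::filtfilt(bf, x)
    rec$data[i, ] <- x
  }
  rec
}

#' Select background segments away from annotated events
#'
#' Tiles the recording with non-overlapping windows of `seg_len_s` seconds
#' (deterministic left-to-right scan from the first sample) and keeps a
#' window only if every one of its samples is at least `min_gap_s` away from
#' every annotated generalized-spike or artifact onset. The count can be
#' capped; with `subsample_seed` the cap is enforced by a seeded random
#' subsample instead of truncation.
#'
#' @param rec An `eeg_recording` (its `annotations` may be empty).
#' @param seg_len_s Segment length in seconds (default 1).
#' @param min_gap_s Minimum distance of any segment sample to any event
#'   onset, in seconds (default 1).
#' @param max_segments Cap on the number of returned segments.
#' @param subsample_seed Optional seed; if given and more than
#'   `max_segments` windows are eligible, a random subsample (in temporal
#'   order) is taken instead of the first `max_segments`.
#' @return Object of class `segment_set`: list with `segments` (list of
#'   channels x L matrices), `fs`, `n_segments`, `layout`.
#' @export
select_segments <- function(rec, seg_len_s = 1, min_gap_s = 1,
                            max_segments = Inf, subsample_seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(seg_len_s * rec$fs)
  G <- round(min_gap_s * rec$fs)
  n <- ncol(rec$data)
  onsets <- rec$annotations$onset_sample
  starts <- seq(1L, n - L + 1L, by = L)
  ok <- vapply(starts, function(a) {
    # window samples a .. a+L-1 (1-based); onsets are 0-based
    all(onsets <= (a - 1L) - G | onsets >= (a - 1L) + (L - 1L) + G)
  }, logical(1))
  starts <- starts[ok]
  if (length(starts) > max_segments) {
    if (!is.null(subsample_seed))
      starts <- sort(with_seed(subsample_seed,
                               sample(starts, max_segments)))
    else starts <- starts[seq_len(max_segments)]
  }
  segs <- lapply(starts, function(a) rec$data[, a:(a + L - 1L), drop = FALSE])
  structure(list(segments = segs, fs = rec$fs, n_segments = length(segs),
                 start_samples = starts, layout = rec$layout),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", x$n_segments, " segment(s) of ",
      if (x$n_segments) ncol(x$segments[[1]]) else 0,
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
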