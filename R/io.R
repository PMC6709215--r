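channel_names <- function(n) sprintf("ch%02d", seq_len(n))

#' Write / read a recording as CSV + JSON sidecar
#'
#' The signal goes to `<prefix>.csv` (samples as rows, one column per
#' channel); sampling rate, channel names, electrode layout and event
#' annotations go to `<prefix>.json`.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Path prefix (without extension).
#' @return `write_recording()` returns the two paths invisibly;
#'   `read_recording()` returns the reconstructed `eeg_recording` (without
#'   any generating ground truth).
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  csv <- paste0(prefix, ".csv"); json <- paste0(prefix, ".json")
  df <- as.data.frame(t(rec$data))
  names(df) <- channel_names(nrow(rec$data))
  write.csv(df, csv, row.names = FALSE)
  side <- list(fs = rec$fs,
               channels = channel_names(nrow(rec$data)),
               layout = list(positions = unname(rec$layout$positions),
                             contralateral_pair = rec$layout$contralateral_pair,
                             hemisphere = rec$layout$hemisphere),
               annotations = rec$annotations)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pos <- as.matrix(side$layout$positions)
  colnames(pos) <- c("x", "y")
  layout <- structure(list(n_channels = ncol(df), positions = pos,
                           contralateral_pair =
                             as.integer(side$layout$contralateral_pair),
                           hemisphere = side$layout$hemisphere),
                      class = "electrode_layout")
  ann <- as.data.frame(side$annotations)
  if (!nrow(ann))
    ann <- data.frame(event_type = character(), onset_sample = integer())
  dat <- t(as.matrix(df))
  dimnames(dat) <- NULL
  new_recording(dat, side$fs, layout, ann)
}

#' Write / read a connectivity matrix as CSV + JSON metadata
#'
#' The weight matrix goes to `path` (rows = source channels, header =
#' channel names); method, normalization state and segment count go to the
#' matching `.json` file.
#'
#' @param C A `connectivity_matrix`.
#' @param path CSV path (the metadata path swaps the extension for
#'   `.json`).
#' @export
write_connectivity <- function(C, path) {
  stopifnot(inherits(C, "connectivity_matrix"))
  df <- as.data.frame(C$weights)
  names(df) <- channel_names(ncol(C$weights))
  write.csv(df, path, row.names = FALSE)
  meta <- list(method = C$method, normalized = C$normalized,
               n_segments_used = C$n_segments_used)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  W <- as.matrix(read.csv(path))
  dimnames(W) <- NULL
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  new_connectivity_matrix(W, meta$method, meta$normalized,
                          meta$n_segments_used)
}
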