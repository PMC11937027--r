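#' Construct an EEG clip
#'
#' An EEG clip is a fixed-duration block of multichannel scalp EEG: a
#' channels-by-samples matrix of voltages (microvolts) together with the
#' sampling rate and the ordered montage labels. One clip is the unit that is
#' turned into one attributed graph downstream.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique montage names, one per
#'   channel, in row order.
#' @return An object of class `eeg_clip` with elements `signal`, `fs`,
#'   `channel_labels`.
#' @export
#' @examples
#' clip <- eeg_clip(matrix(rnorm(4 * 100), 4), fs = 100,
#'                  channel_labels = c("Fp1", "Fp2", "O1", "O2"))
#' dim(clip$signal)
eeg_clip <- function(signal, fs, channel_labels = NULL) {
  stop_if_not_matrix(signal, "signal")
  if (nrow(signal) < 2) stop("an EEG clip needs at least 2 channels", call. = FALSE)
  if (ncol(signal) < 2) stop("an EEG clip needs at least 2 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(signal) %||% sprintf("ch%02d", seq_len(nrow(signal)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal)) {
    stop("`channel_labels` length must equal the channel count", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be unique", call. = FALSE)
  }
  if (!all(is.finite(signal))) stop("clip signal contains non-finite values", call. = FALSE)
  rownames(signal) <- channel_labels
  structure(list(signal = signal, fs = fs, channel_labels = channel_labels),
            class = "eeg_clip")
}

#' @export
print.eeg_clip <- function(x, ...) {
  cat(sprintf("<eeg_clip> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Split a recording into non-overlapping clips
#'
#' Windows a long multichannel recording into consecutive disjoint clips of
#' fixed duration; a trailing remainder shorter than the window is dropped.
#'
#' @param clip An [eeg_clip] holding the full recording.
#' @param duration Window length in seconds (default 12).
#' @return List of `eeg_clip` objects.
#' @export
clip_windows <- function(clip, duration = 12) {
  stopifnot(inherits(clip, "eeg_clip"), duration > 0)
  w <- floor(duration * clip$fs)
  if (w < 2) stop("window shorter than 2 samples", call. = FALSE)
  n <- floor(ncol(clip$signal) / w)
  if (n < 1) stop("recording shorter than one window", call. = FALSE)
  lapply(seq_len(n), function(i) {
    eeg_clip(clip$signal[, ((i - 1) * w + 1):(i * w), drop = FALSE],
             fs = clip$fs, channel_labels = clip$channel_labels)
  })
}

#' Read a continuous EDF recording
#'
#' Minimal reader for plain continuous European Data Format files (ASCII
#' header, 16-bit little-endian samples, per-signal physical/digital scaling).
#' Annotation channels ("EDF Annotations") are dropped. All retained signals
#' must share one sampling rate.
#'
#' @param path Path to an .edf file.
#' @return An [eeg_clip] in the file's signal order, in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                      # version
  hdr(80); hdr(80)            # patient / recording id
  hdr(8); hdr(8)              # start date / time
  as.integer(hdr(8))          # header bytes
  hdr(44)                     # reserved
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF header", call. = FALSE)
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- field(16)
  field(80); field(8)                      # transducer, physical dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                                # prefiltering
  nsamp <- as.integer(field(8))
  field(32)                                # reserved
  keep <- labels != "EDF Annotations"
  if (n_rec < 0) stop("EDF with unknown record count is not supported", call. = FALSE)
  per_rec <- sum(nsamp)
  raw <- readBin(con, "integer", n = per_rec * n_rec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < per_rec * n_rec) stop("truncated EDF data record section", call. = FALSE)
  offs <- c(0, cumsum(nsamp))
  sig <- lapply(which(keep), function(i) {
    idx <- unlist(lapply(seq_len(n_rec) - 1L, function(r) {
      r * per_rec + offs[i] + seq_len(nsamp[i])
    }))
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    pmin[i] + gain * (raw[idx] - dmin[i])
  })
  rates <- nsamp[keep] / rec_dur
  if (length(unique(rates)) != 1) {
    stop("EDF signals with mixed sampling rates are not supported", call. = FALSE)
  }
  eeg_clip(do.call(rbind, sig), fs = rates[1], channel_labels = labels[keep])
}
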