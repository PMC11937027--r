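#' Per-channel feature extraction
#'
#' Maps a clip to the N x D feature matrix X that attributes the EEG graph.
#' The pipeline is agnostic to the exact featurization; the default is
#' spectral: the log-magnitude of the first `D` non-DC frequency bins
#' of each channel's discrete Fourier transform, z-scored per channel, which
#' captures the band-power profile commonly used for EEG graphs. `raw` mode
#' instead uniformly downsamples the z-scored time series to length `D`.
#'
#' Channels with (near-)zero variance are floored at an internal epsilon
#' rather than producing NaN; a warning reports the affected channels.
#'
#' @param clip An [eeg_clip].
#' @param mode `"spectral"` (default) or `"raw"`.
#' @param D Feature dimension; must satisfy `D <= samples/2` for spectral and
#'   `D <= samples` for raw mode.
#' @return N x D numeric matrix, rows named by channel label.
#' @export
extract_features <- function(clip, mode = c("spectral", "raw"), D = 64) {
  stopifnot(inherits(clip, "eeg_clip"))
  mode <- match.arg(mode)
  S <- clip$signal
  n <- ncol(S)
  if (mode == "spectral") {
    if (D > n / 2) stop("spectral mode requires D <= samples/2", call. = FALSE)
    # mvfft works on columns; bins 2..(D+1) skip the DC offset
    sp <- stats::mvfft(t(S))
    X <- t(log(Mod(sp[2:(D + 1), , drop = FALSE]) + EPS))
  } else {
    if (D > n) stop("raw mode requires D <= samples", call. = FALSE)
    idx <- round(seq(1, n, length.out = D))
    X <- S[, idx, drop = FALSE]
  }
  X <- zscore_rows(X)
  rownames(X) <- clip$channel_labels
  colnames(X) <- NULL
  X
}

# Row-wise z-score with variance floored at EPS (constant rows become 0).
zscore_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- sqrt(rowMeans((X - mu)^2))
  low <- sdv < sqrt(EPS)
  if (any(low)) {
    warning(sprintf("%d channel(s) with (near-)zero variance; variance floored", sum(low)))
    sdv[low] <- sqrt(EPS)
  }
  (X - mu) / sdv
}
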