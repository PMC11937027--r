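#' Synthetic normal-EEG generator specification
#'
#' The generator emulates resting multichannel scalp EEG at the level the
#' detector consumes: each channel is a mixture of a few band-limited
#' stochastic latent sources plus white sensor noise. Sources are placed on
#' the unit sphere and mixed into channels with a nonnegative squared-
#' exponential spatial profile (a crude stand-in for volume conduction), so
#' nearby channels share sources and are positively correlated — which makes
#' the correlation and transfer-function graphs non-trivial.
#'
#' @param N Channels (default 19, the 10-20 montage).
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Clip length in seconds (default 12).
#' @param n_sources Latent source count (default 4).
#' @param mixing Optional N x n_sources nonnegative mixing matrix; by default
#'   drawn once from the spatial profile using `seed`.
#' @param noise_sd White-noise SD relative to unit-variance sources
#'   (default 0.1).
#' @param labels Channel labels (default: the 10-20 montage when N = 19).
#' @param seed Seed for the default mixing matrix.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(N = 19, fs = 250, duration = 12, n_sources = 4,
                           mixing = NULL, noise_sd = 0.1, labels = NULL,
                           seed = 1) {
  stopifnot(N >= 2, fs > 0, duration > 0, n_sources >= 1, noise_sd >= 0)
  labels <- labels %||% if (N == 19) montage_1020_labels() else sprintf("ch%02d", seq_len(N))
  if (is.null(mixing)) {
    coords <- if (N == 19) standard_1020_layout(labels)$coords else {
      ang <- 2 * pi * (seq_len(N) - 1) / N
      cbind(cos(ang), sin(ang), 0)
    }
    mixing <- with_seed(seed, {
      src <- matrix(stats::rnorm(n_sources * 3), n_sources, 3)
      src <- src / sqrt(rowSums(src^2))
      d2 <- outer(seq_len(N), seq_len(n_sources),
                  Vectorize(function(i, j) sum((coords[i, ] - src[j, ])^2)))
      exp(-d2 / 0.5)
    })
  }
  stopifnot(nrow(mixing) == N, ncol(mixing) == n_sources, all(mixing >= 0))
  structure(list(N = N, fs = fs, duration = duration, n_sources = n_sources,
                 mixing = mixing, noise_sd = noise_sd, labels = labels,
                 seed = seed), class = "generator_spec")
}

# One unit-variance band-limited source: band-pass filtered white noise.
band_source <- function(n, fs) {
  lo <- stats::runif(1, 1, 20)
  hi <- lo + stats::runif(1, 2, 10)
  ny <- fs / 2
  bf <- signal::butter(2, c(lo, min(hi, ny * 0.95)) / ny, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]          # drop filter edge transients
  x / max(stats::sd(x), EPS)
}

#' Generate one synthetic normal clip
#'
#' Deterministic given `seed`. Channels sharing sources (similar mixing rows)
#' come out correlated at lag zero.
#' @param spec A [generator_spec].
#' @param seed Integer seed.
#' @return An [eeg_clip].
#' @export
generate_normal_clip <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- round(spec$fs * spec$duration)
  with_seed(seed, {
    S <- vapply(seq_len(spec$n_sources), function(j) band_source(n, spec$fs),
                numeric(n))                       # n x n_sources
    sig <- spec$mixing %*% t(S) +
      spec$noise_sd * matrix(stats::rnorm(spec$N * n), spec$N, n)
    eeg_clip(sig, fs = spec$fs, channel_labels = spec$labels)
  })
}

#' Average consecutive clips' feature matrices
#'
#' Elementwise mean over consecutive disjoint blocks of `window` feature
#' matrices (default 35); a trailing remainder shorter than the window is
#' dropped. Averaging smooths idiosyncratic clip noise so an injected
#' corruption stands out against a stable background.
#'
#' @param clips List of equal-shape feature matrices.
#' @param window Block size (default 35).
#' @return List of `length(clips) %/% window` averaged feature matrices.
#' @export
average_clips <- function(clips, window = 35) {
  stopifnot(window >= 1)
  if (length(clips) < window) stop("fewer clips than one averaging window", call. = FALSE)
  n_out <- length(clips) %/% window
  lapply(seq_len(n_out), function(b) {
    block <- clips[((b - 1) * window + 1):(b * window)]
    Reduce(`+`, block) / window
  })
}

#' Inject a structural + contextual corruption into a graph
#'
#' With probability `p_inject`, one node is selected uniformly and corrupted
#' both ways at once: *structurally* by connecting it to every other node
#' (its off-diagonal adjacency row and column set to 1) and *contextually* by
#' replacing its feature row with that of the node at the largest Euclidean
#' feature distance. At most one node per clip is corrupted.
#'
#' @param graph An `eeg_graph` (raw, unnormalized adjacency).
#' @param p_inject Corruption probability per clip.
#' @param seed Integer seed.
#' @return List: `graph` (possibly corrupted), `node_labels` (binary length-N,
#'   marking the corrupted node).
#' @export
inject_anomaly <- function(graph, p_inject, seed = 1) {
  stopifnot(inherits(graph, "eeg_graph"), p_inject >= 0, p_inject <= 1)
  N <- nrow(graph$X)
  if (N < 2) stop("injection needs at least 2 nodes", call. = FALSE)
  labels <- integer(N)
  with_seed(seed, {
    if (stats::runif(1) < p_inject) {
      i <- sample.int(N, 1)
      labels[i] <- 1L
      A <- graph$A$A
      A[i, -i] <- 1
      A[-i, i] <- 1
      d2 <- rowSums((graph$X - matrix(graph$X[i, ], N, ncol(graph$X), byrow = TRUE))^2)
      far <- which.max(d2)
      X <- graph$X
      X[i, ] <- X[far, ]
      graph <- eeg_graph(new_adjacency(A, graph$A$kind,
                                       c(graph$A$params, list(corrupted_node = i))),
                         X, graph$labels)
    }
  })
  list(graph = graph, node_labels = labels)
}

#' Build the synthetic corruption benchmark
#'
#' The full protocol: generate `n_clips` normal clips, extract features,
#' average every `window` consecutive clips, build one graph per averaged
#' clip, then independently corrupt each averaged clip with probability
#' `p_inject`. Clip label = 1 iff any node label = 1. Byte-identical given
#' one seed.
#'
#' @param spec A [generator_spec].
#' @param n_clips Number of raw normal clips (>= `window`).
#' @param window Averaging window (default 35).
#' @param p_inject Per-averaged-clip corruption probability (default 0.03).
#' @param graph_kind Adjacency variant for the per-clip graphs
#'   (default `"corr"`).
#' @param feature_mode,D Feature extraction settings ([extract_features]).
#' @param seed Integer seed driving everything.
#' @return A `gca_benchmark` list: `graphs` (possibly corrupted `eeg_graph`s),
#'   `clean_graphs`, `node_labels` (list of binary vectors), `clip_labels`,
#'   and a `params` record of every setting.
#' @export
make_benchmark <- function(spec, n_clips, window = 35, p_inject = 0.03,
                           graph_kind = "corr", feature_mode = "spectral",
                           D = 64, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"), n_clips >= window)
  n_avg <- n_clips %/% window
  layout <- if (spec$N == 19) standard_1020_layout(spec$labels) else NULL
  # derive independent sub-seeds from one stream
  sub <- with_seed(seed, sample.int(.Machine$integer.max, n_clips + 2 * n_avg))
  feats <- lapply(seq_len(n_clips), function(i) {
    extract_features(generate_normal_clip(spec, seed = sub[i]),
                     mode = feature_mode, D = D)
  })
  averaged <- average_clips(feats, window)
  graphs <- node_labels <- vector("list", n_avg)
  clean <- vector("list", n_avg)
  for (b in seq_len(n_avg)) {
    A <- build_graph(graph_kind, averaged[[b]], layout = layout)
    g <- eeg_graph(A, averaged[[b]], labels = spec$labels)
    clean[[b]] <- g
    inj <- inject_anomaly(g, p_inject, seed = sub[n_clips + n_avg + b])
    graphs[[b]] <- inj$graph
    node_labels[[b]] <- inj$node_labels
  }
  structure(list(
    graphs = graphs, clean_graphs = clean, node_labels = node_labels,
    clip_labels = vapply(node_labels, function(x) as.integer(any(x == 1)), 0L),
    averaged_clips = averaged,
    params = list(N = spec$N, fs = spec$fs, duration = spec$duration,
                  n_sources = spec$n_sources, noise_sd = spec$noise_sd,
                  n_clips = n_clips, window = window, p_inject = p_inject,
                  graph_kind = graph_kind, feature_mode = feature_mode, D = D,
                  seed = seed)
  ), class = "gca_benchmark")
}

#' @export
print.gca_benchmark <- function(x, ...) {
  cat(sprintf("<gca_benchmark> %d averaged clips (%d corrupted), kind=%s, seed=%s\n",
              length(x$graphs), sum(x$clip_labels), x$params$graph_kind,
              x$params$seed))
  invisible(x)
}
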