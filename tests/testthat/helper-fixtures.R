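# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately naive double-loop implementations, kept separate
# from the package's vectorized code paths.

make_clip <- function(N = 4, n = 100, fs = 100, seed = 1) {
  set.seed(seed)
  eeg_clip(matrix(rnorm(N * n), N, n), fs = fs,
           channel_labels = sprintf("ch%02d", seq_len(N)))
}

rand_graph_instance <- function(N = 8, D = 16, seed = 1, kind = "corr") {
  set.seed(seed)
  X <- matrix(rnorm(N * D), N, D)
  eeg_graph(build_graph(kind, X), X)
}

tiny_params <- function(D = 5, h = 6, d = 3, L = 2, hidden = 4, seed = 7) {
  gca_params(D, h = h, d = d, L = L, hidden = hidden, seed = seed)
}

# -- graph-builder oracles ----------------------------------------------------

bf_pearson <- function(X) {
  n <- nrow(X)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- X[i, ] - mean(X[i, ])
      xj <- X[j, ] - mean(X[j, ])
      W[i, j] <- sum(xi * xj) / (max(sqrt(sum(xi^2)), 1e-8) *
                                   max(sqrt(sum(xj^2)), 1e-8))
    }
  }
  W
}

bf_top_m <- function(W, i, m = 3) {
  js <- setdiff(seq_len(nrow(W)), i)
  js[order(-abs(W[i, js]), js)][seq_len(min(m, length(js)))]
}

bf_dist_graph <- function(V, tau, k) {
  n <- nrow(V)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dd <- sqrt(sum((V[i, ] - V[j, ])^2))
      A[i, j] <- if (dd <= k) exp(-dd^2 / tau) else 0
    }
  }
  diag(A) <- 1
  A
}

bf_corr_graph <- function(X, m = 3) {
  W <- bf_pearson(X)
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    keep <- bf_top_m(W, i, m)
    A[i, keep] <- W[i, keep]
  }
  A
}

bf_dtf_graph <- function(X, m = 3) {
  W <- bf_pearson(X)
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    keep <- bf_top_m(W, i, m)
    for (j in keep) {
      denom <- 0
      for (mm in seq_len(n)) if (mm != i && mm != j) denom <- denom + W[i, mm]^2
      A[i, j] <- W[i, j] / max(denom, 1e-8)
    }
  }
  A
}

bf_normalize <- function(A, self_loops = TRUE) {
  M <- if (self_loops) A + diag(nrow(A)) else A
  s <- 1 / sqrt(rowSums(abs(M)))
  diag(s) %*% M %*% diag(s)
}

# -- metric oracles -----------------------------------------------------------

bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# -- minimal EDF writer (text-free binary built at test time) -----------------

write_test_edf <- function(path, sig, fs) {
  ns <- nrow(sig)
  n <- ncol(sig)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  # integer physical bounds keep every header field inside its 8-char slot
  pmin_v <- floor(apply(sig, 1, min))
  pmax_v <- ceiling(apply(sig, 1, max))
  pmax_v <- ifelse(pmax_v == pmin_v, pmin_v + 1, pmax_v)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                   pad("01.01.20", 8), pad("00.00.00", 8),
                   pad(256 * (ns + 1), 8), pad("", 44), pad(1, 8),
                   pad(format(n / fs), 8), pad(ns, 4)),
            con, eos = NULL)
  field <- function(vals, w) {
    writeChar(paste0(vapply(vals, pad, "", w = w), collapse = ""), con, eos = NULL)
  }
  field(rownames(sig), 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(format(pmin_v), 8)
  field(format(pmax_v), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(n, ns), 8)
  field(rep("", ns), 32)
  for (i in seq_len(ns)) {
    dig <- round((sig[i, ] - pmin_v[i]) / (pmax_v[i] - pmin_v[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
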