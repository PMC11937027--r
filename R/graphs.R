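#' @name eeg_graphs
#' @title EEG graph construction
#'
#' @description
#' An EEG clip becomes an attributed graph `G = {A, X}`: `A` is an N x N
#' adjacency over channels and `X` the N x D feature matrix. Six adjacency
#' variants are supported, each encoding a different prior about inter-channel
#' structure:
#'
#' * `dist` — Gaussian kernel of inter-electrode Euclidean distance, zeroed
#'   beyond a cutoff `k`; fixed across clips for a fixed cap.
#' * `corr` — normalized cross-correlation between feature rows, sparsified to
#'   each node's top-3 neighbors by absolute weight (functional connectivity).
#' * `rand` — all off-diagonals 0.5 (all channels equal contributors).
#' * `full` — all entries 1.
#' * `dtf`  — correlation normalized by each row's total squared correlation
#'   to third channels, on the same top-3 support as `corr` (mutual-influence
#'   flavour of functional connectivity).
#' * `identity` — the identity matrix: no inter-channel relationships. Feeding
#'   it to the encoder yields the "semantic" per-channel view.
#'
#' All builders are deterministic. `corr`/`dtf` weights can be signed; the
#' top-3 ranking uses absolute values with ties broken by lower channel index.
NULL

new_adjacency <- function(A, kind, params = list()) {
  dimnames(A) <- NULL
  structure(list(A = A, kind = kind, params = params), class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  cat(sprintf("<eeg_adjacency> kind=%s, %d nodes\n", x$kind, nrow(x$A)))
  invisible(x)
}

#' Pair an adjacency with a feature matrix
#' @param A An `eeg_adjacency`.
#' @param X N x D feature matrix ([extract_features]); row count must match.
#' @param labels Optional channel labels carried for export.
#' @return An `eeg_graph` list `{A, X, labels}`.
#' @export
eeg_graph <- function(A, X, labels = NULL) {
  stopifnot(inherits(A, "eeg_adjacency"))
  stop_if_not_matrix(X, "X")
  if (nrow(A$A) != nrow(X)) stop("adjacency and feature row counts differ", call. = FALSE)
  labels <- labels %||% rownames(X) %||% sprintf("ch%02d", seq_len(nrow(X)))
  structure(list(A = A, X = X, labels = as.character(labels)), class = "eeg_graph")
}

#' Distance EEG graph
#'
#' `a_ij = exp(-||v_i - v_j||^2 / tau)` when the electrodes are within
#' Euclidean distance `k`, else 0. Encodes the fixed cap geometry; the same
#' matrix serves every clip recorded with the layout.
#'
#' @param layout An `electrode_layout` ([standard_1020_layout]).
#' @param tau Positive kernel scale (same squared units as the unit-sphere
#'   coordinates); default 1.
#' @param k Distance cutoff; default 0.9 (unit-sphere units).
#' @return `eeg_adjacency`, kind `"dist"`; symmetric, unit diagonal.
#' @export
build_dist_graph <- function(layout, tau = 1.0, k = 0.9) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  V <- layout$coords
  n <- nrow(V)
  if (n < 2) stop("need at least 2 electrodes", call. = FALSE)
  d2 <- as.matrix(stats::dist(V))^2
  A <- exp(-d2 / tau)
  A[sqrt(d2) > k] <- 0
  diag(A) <- 1
  new_adjacency(A, "dist", list(tau = tau, k = k))
}

# Pairwise normalized lag-zero cross-correlation of feature rows: the
# mean-centered dot product over the product of centered norms (Pearson r),
# with degenerate rows floored at EPS.
row_corr <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  nrm <- pmax(nrm, EPS)
  C <- (Xc %*% t(Xc)) / (nrm %o% nrm)
  dimnames(C) <- NULL
  C
}

# Row-wise top-m support by |w| off the diagonal, ties to lower index.
topk_mask <- function(W, m = 3) {
  n <- nrow(W)
  M <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    keep <- j[order(-abs(W[i, j]), j)][seq_len(min(m, length(j)))]
    M[i, keep] <- TRUE
  }
  M
}

#' Correlation EEG graph
#'
#' Functional-connectivity adjacency: the normalized cross-correlation between
#' the two channels' feature rows, kept only on each node's top-3 neighborhood
#' (by absolute correlation) to avoid an overly connected graph; zero diagonal.
#'
#' @param X N x D feature matrix.
#' @param m Neighborhood size (default 3). With `N <= m + 1` all off-diagonal
#'   entries are kept and a warning is issued.
#' @return `eeg_adjacency`, kind `"corr"`.
#' @export
build_corr_graph <- function(X, m = 3) {
  stop_if_not_matrix(X, "X")
  n <- nrow(X)
  W <- row_corr(X)
  if (n <= m + 1) {
    warning("too few channels for top-", m, " sparsification; keeping all edges")
    A <- W
    diag(A) <- 0
  } else {
    A <- ifelse(topk_mask(W, m), W, 0)
    diag(A) <- 0
  }
  new_adjacency(A, "corr", list(m = m))
}

#' Random EEG graph
#'
#' Every pair of channels connected with weight 0.5, unit diagonal: all
#' electrodes assumed interconnected and equal contributors.
#' @param N Channel count (>= 1).
#' @return `eeg_adjacency`, kind `"rand"`.
#' @export
build_rand_graph <- function(N) {
  stopifnot(N >= 1)
  A <- matrix(0.5, N, N)
  diag(A) <- 1
  new_adjacency(A, "rand", list())
}

#' Full EEG graph
#'
#' All entries 1 (including the diagonal).
#' @param N Channel count (>= 1).
#' @return `eeg_adjacency`, kind `"full"`.
#' @export
build_full_graph <- function(N) {
  stopifnot(N >= 1)
  new_adjacency(matrix(1, N, N), "full", list())
}

#' Transfer-function EEG graph
#'
#' `a_ij = corr(X_i, X_j) / sum_{m != i,j} corr(X_i, X_m)^2` on the same
#' top-3 neighborhood as the correlation graph, zero elsewhere. The
#' denominator (floored at an internal epsilon) rescales each pairwise
#' correlation by the target row's total squared correlation with third
#' channels, a directed mutual-influence weighting.
#'
#' @inheritParams build_corr_graph
#' @return `eeg_adjacency`, kind `"dtf"`.
#' @export
build_dtf_graph <- function(X, m = 3) {
  stop_if_not_matrix(X, "X")
  n <- nrow(X)
  if (n < 3) stop("DTF graph requires >= 3 channels", call. = FALSE)
  W <- row_corr(X)
  mask <- if (n <= m + 1) {
    warning("too few channels for top-", m, " sparsification; keeping all edges")
    matrix(TRUE, n, n) & !diag(n)
  } else {
    topk_mask(W, m)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && mask[i, j]) {
        denom <- sum(W[i, setdiff(seq_len(n), c(i, j))]^2)
        A[i, j] <- W[i, j] / max(denom, EPS)
      }
    }
  }
  new_adjacency(A, "dtf", list(m = m))
}

#' Identity graph
#'
#' The identity matrix: no relationships between channels. Encoding `{I, X}`
#' gives each channel's own-feature ("semantic") view.
#' @param N Channel count (>= 1).
#' @return `eeg_adjacency`, kind `"identity"`.
#' @export
build_identity_graph <- function(N) {
  stopifnot(N >= 1)
  new_adjacency(diag(N), "identity", list())
}

#' Build any adjacency variant by name
#'
#' @param kind One of `"dist"`, `"corr"`, `"rand"`, `"full"`, `"dtf"`,
#'   `"identity"`.
#' @param X Feature matrix (needed by `corr`/`dtf`; supplies N otherwise).
#' @param layout Electrode layout (needed by `dist`).
#' @param tau,k Distance-graph parameters.
#' @return `eeg_adjacency`.
#' @export
build_graph <- function(kind, X, layout = NULL, tau = 1.0, k = 0.9) {
  switch(kind,
    dist = build_dist_graph(layout %||% standard_1020_layout(rownames(X)), tau, k),
    corr = build_corr_graph(X),
    rand = build_rand_graph(nrow(X)),
    full = build_full_graph(nrow(X)),
    dtf = build_dtf_graph(X),
    identity = build_identity_graph(nrow(X)),
    stop(sprintf("unknown graph kind '%s'", kind), call. = FALSE)
  )
}

#' Symmetric GCN normalization
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal degree matrix
#' of the (optionally self-looped) adjacency — the propagation operator of a
#' graph convolution layer. Degrees are sums of *absolute* weights, so signed
#' correlation graphs cannot cancel a row's degree to zero; for nonnegative
#' adjacencies this is the ordinary degree. Self loops are added by default
#' for the EEG variants (the sparse correlation graphs can otherwise have
#' zero-degree rows); the identity graph passes through unchanged.
#'
#' @param A An `eeg_adjacency` or plain numeric matrix.
#' @param add_self_loops Add `I` before normalizing (default `TRUE`; ignored —
#'   effectively `FALSE` — for `kind == "identity"`, which is already its own
#'   normalization).
#' @return Object of the same type as `A` with normalized entries.
#' @export
normalize_adjacency <- function(A, add_self_loops = TRUE) {
  adj <- inherits(A, "eeg_adjacency")
  M <- if (adj) A$A else A
  stop_if_not_matrix(M, "A")
  if (adj && A$kind == "identity") return(A)
  if (add_self_loops) M <- M + diag(nrow(M))
  # degrees from absolute weights: on signed graphs (corr/dtf) a signed degree
  # can cancel to ~0 and blow up D^{-1/2}; for nonnegative graphs identical
  deg <- rowSums(abs(M))
  if (any(deg <= 0)) {
    stop("zero node degree; cannot normalize (consider add_self_loops = TRUE)",
         call. = FALSE)
  }
  s <- 1 / sqrt(deg)
  Mn <- M * (s %o% s)
  if (adj) new_adjacency(Mn, A$kind, c(A$params, list(normalized = TRUE))) else Mn
}

#' Export a graph as CSV files or a JSON document
#'
#' `write_graph_csv` writes `<stem>_A.csv` and `<stem>_X.csv` with channel
#' labels as header; `write_graph_json` writes one self-describing document
#' `{kind, params, labels, A, X}`.
#'
#' @param graph An `eeg_graph`.
#' @param stem,path Output locations.
#' @return The written path(s), invisibly.
#' @export
write_graph_csv <- function(graph, stem) {
  stopifnot(inherits(graph, "eeg_graph"))
  a_path <- paste0(stem, "_A.csv")
  x_path <- paste0(stem, "_X.csv")
  A <- graph$A$A
  colnames(A) <- graph$labels
  utils::write.csv(A, a_path, row.names = FALSE)
  X <- t(graph$X)
  colnames(X) <- graph$labels
  utils::write.csv(X, x_path, row.names = FALSE)
  invisible(c(a_path, x_path))
}

#' @rdname write_graph_csv
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "eeg_graph"))
  doc <- list(kind = graph$A$kind, params = graph$A$params,
              labels = graph$labels, A = graph$A$A, X = graph$X)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a JSON graph document
#' @param path Path written by [write_graph_json].
#' @return An `eeg_graph`.
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- new_adjacency(as.matrix(doc$A), doc$kind, as.list(doc$params))
  eeg_graph(A, as.matrix(doc$X), labels = doc$labels)
}
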