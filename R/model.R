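#' Model parameters for the weight-sharing variational graph encoder
#'
#' The encoder is one shared hidden GCN layer feeding two variational-head GCN
#' layers (mean and log-variance). The *same* weights serve both forward
#' passes: the structural view `{A, X}` (graph aggregation) and the semantic
#' view `{I, X}` (identity aggregation) — weight sharing is what makes the two
#' views' embeddings comparable. The decoder is an L-layer MLP mapping the
#' fused embedding back to node attributes; structure is reconstructed from
#' the fused embedding's Gram matrix.
#'
#' @param D Input feature dimension.
#' @param h Hidden GCN width (default 64).
#' @param d Embedding dimension (default 32).
#' @param L Decoder depth (default 2).
#' @param hidden Decoder hidden width (default 64).
#' @param seed Seed for the Glorot-uniform initialization.
#' @return A `gca_params` list of weight matrices: `W1` (D x h), `Wmu`, `Wsig`
#'   (h x d), decoder `Wd`/`bd` lists, plus a `dims` record.
#' @export
gca_params <- function(D, h = 64, d = 32, L = 2, hidden = 64, seed = 1) {
  stopifnot(D >= 1, h >= 1, d >= 1, L >= 1)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  dec_dims <- c(d, if (L > 1) rep(hidden, L - 1), D)
  with_seed(seed, {
    p <- list(
      W1 = glorot(D, h),
      Wmu = glorot(h, d),
      Wsig = glorot(h, d),
      Wd = lapply(seq_len(L), function(l) glorot(dec_dims[l], dec_dims[l + 1])),
      bd = lapply(seq_len(L), function(l) rep(0, dec_dims[l + 1])),
      dims = list(D = D, h = h, d = d, L = L, hidden = hidden),
      activation = "relu"
    )
    class(p) <- "gca_params"
    p
  })
}

relu <- function(x) pmax(x, 0)

#' One graph convolution layer
#'
#' `phi(A_norm %*% X %*% W)`: neighbor aggregation through an already
#' normalized propagation matrix, a shared linear map, and an activation.
#' With `A_norm = I` this is the per-channel (identity-aggregation) transform.
#'
#' @param X Input node matrix (N x Din).
#' @param A_norm Normalized propagation matrix (N x N), e.g. from
#'   [normalize_adjacency]; an `eeg_adjacency` is accepted.
#' @param W Weight matrix (Din x Dout).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return N x Dout matrix.
#' @export
gcn_layer <- function(X, A_norm, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (inherits(A_norm, "eeg_adjacency")) A_norm <- A_norm$A
  stop_if_not_matrix(X, "X"); stop_if_not_matrix(W, "W")
  if (ncol(A_norm) != nrow(X)) stop("A_norm / X shape mismatch", call. = FALSE)
  if (ncol(X) != nrow(W)) stop("X / W shape mismatch", call. = FALSE)
  out <- A_norm %*% X %*% W
  if (activation == "relu") relu(out) else out
}

#' Encode one graph view into per-node Gaussian posteriors
#'
#' Runs the shared hidden GCN layer and the two (linear) variational heads:
#' `H = relu(P X W1)`, `mu = P H Wmu`, `log_var = P H Wsig`, where `P` is the
#' normalized propagation matrix of the view. Encoding `{A, X}` gives the
#' structural posterior; encoding `{I, X}` with the *same* params gives the
#' semantic posterior.
#'
#' @param graph An `eeg_graph` (adjacency will be normalized if not already).
#' @param params `gca_params`.
#' @return A `gca_posterior`: list `mu`, `log_var` (N x d), `view`
#'   (`"semantic"` for the identity kind, else `"structural"`).
#' @export
encode <- function(graph, params) {
  stopifnot(inherits(graph, "eeg_graph"), inherits(params, "gca_params"))
  P <- normalize_adjacency(graph$A)$A
  X <- graph$X
  H <- relu(P %*% X %*% params$W1)
  M <- P %*% H
  mu <- M %*% params$Wmu
  log_var <- M %*% params$Wsig
  if (!all(is.finite(mu)) || !all(is.finite(log_var))) {
    stop("non-finite encoder output (training divergence?)", call. = FALSE)
  }
  structure(list(mu = mu, log_var = log_var,
                 view = if (graph$A$kind == "identity") "semantic" else "structural"),
            class = "gca_posterior")
}

#' Reparameterized sample from a posterior
#'
#' `Z = mu + exp(log_var / 2) * eta`, `eta ~ N(0, 1)` drawn from the seeded
#' stream; deterministic given the seed. In the zero-variance limit the sample
#' equals the mean.
#'
#' @param post A `gca_posterior`.
#' @param seed Integer seed (optional; uses the current RNG stream if `NULL`).
#' @return N x d embedding matrix.
#' @export
sample_embedding <- function(post, seed = NULL) {
  stopifnot(inherits(post, "gca_posterior"))
  eta <- with_seed(seed, matrix(stats::rnorm(length(post$mu)), nrow(post$mu)))
  post$mu + exp(post$log_var / 2) * eta
}

#' Fuse the structural and semantic embeddings
#'
#' Elementwise sum `Z_f = Z_st + Z_se`, combining each node's own-feature
#' information with its neighbor-aggregated information for reconstruction.
#' @param Z_st,Z_se Equal-shape embedding matrices.
#' @return N x d fused embedding.
#' @export
fuse <- function(Z_st, Z_se) {
  stop_if_not_matrix(Z_st, "Z_st"); stop_if_not_matrix(Z_se, "Z_se")
  if (!all(dim(Z_st) == dim(Z_se))) stop("embedding shape mismatch", call. = FALSE)
  Z_st + Z_se
}

# Decoder forward returning intermediates (for backprop).
decoder_forward <- function(Zf, params) {
  L <- params$dims$L
  Hs <- vector("list", L + 1)  # Hs[[l]] = input to layer l
  Us <- vector("list", L)
  Hs[[1]] <- Zf
  for (l in seq_len(L)) {
    U <- Hs[[l]] %*% params$Wd[[l]] +
      matrix(params$bd[[l]], nrow(Zf), length(params$bd[[l]]), byrow = TRUE)
    Us[[l]] <- U
    Hs[[l + 1]] <- if (l < L) relu(U) else U
  }
  list(X_hat = Hs[[L + 1]], Hs = Hs, Us = Us)
}

#' Reconstruct node attributes from the fused embedding
#'
#' L-layer MLP with ReLU hidden activations and a linear final layer.
#' @param Z_f Fused embedding (N x d).
#' @param params `gca_params`.
#' @return N x D attribute reconstruction.
#' @export
decode_attributes <- function(Z_f, params) {
  stopifnot(inherits(params, "gca_params"))
  decoder_forward(Z_f, params)$X_hat
}

#' Reconstruct graph structure from the fused embedding
#'
#' Logistic-squashed inner products: `A_hat = sigmoid(Z_f %*% t(Z_f))`, a
#' symmetric matrix with entries in (0, 1).
#' @param Z_f Fused embedding (N x d).
#' @return N x N structure reconstruction.
#' @export
decode_structure <- function(Z_f) {
  stop_if_not_matrix(Z_f, "Z_f")
  1 / (1 + exp(-(Z_f %*% t(Z_f))))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON document (dims, activation, flattened
#' weights at full precision, optional training config and seed); loading
#' reproduces forward passes bit-for-bit.
#'
#' @param params `gca_params`.
#' @param path Output/input path.
#' @param config Optional training configuration to record.
#' @param seed Optional seed to record.
#' @export
gca_save_checkpoint <- function(params, path, config = NULL, seed = NULL) {
  stopifnot(inherits(params, "gca_params"))
  doc <- list(
    dims = params$dims, activation = params$activation,
    W1 = params$W1, Wmu = params$Wmu, Wsig = params$Wsig,
    Wd = params$Wd, bd = params$bd,
    config = config, seed = seed
  )
  # digits = I(17): decimal text that round-trips IEEE doubles exactly, so a
  # reloaded checkpoint reproduces forward passes bit-for-bit
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname gca_save_checkpoint
#' @return `gca_load_checkpoint`: a list with `params`, `config`, `seed`.
#' @export
gca_load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat_list <- function(x) {
    if (is.array(x) && length(dim(x)) == 3) {
      lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
    } else {
      lapply(x, as.matrix)
    }
  }
  as_vec_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else lapply(x, as.numeric)
  }
  p <- list(
    W1 = as.matrix(doc$W1), Wmu = as.matrix(doc$Wmu), Wsig = as.matrix(doc$Wsig),
    Wd = as_mat_list(doc$Wd),
    bd = as_vec_list(doc$bd),
    dims = lapply(doc$dims, as.numeric),
    activation = doc$activation
  )
  class(p) <- "gca_params"
  list(params = p, config = doc$config, seed = doc$seed)
}
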