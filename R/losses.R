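#' Training configuration
#'
#' Assembles the tunables of the training objective. The total loss is
#' `L = L_CCA + L_KL + L_dec` with `L_CCA = L_inv + lambda * L_dco`:
#' a soft-CCA term (invariance between the two normalized views plus a
#' decorrelation penalty that prevents collapsed solutions), KL alignment of
#' both views' per-node Gaussian posteriors to the standard-normal prior, and
#' the attribute + structure reconstruction error.
#'
#' @param lambda Decorrelation trade-off (>= 0, default 0.1).
#' @param weights Length-3 weights for the CCA / KL / reconstruction terms
#'   (default `c(1, 1, 1)`).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 200); each epoch takes one gradient
#'   step per clip (full-batch within a clip).
#' @param sample Draw reparameterized samples during training (default
#'   FALSE: the objective is evaluated on the posterior means, as at test
#'   time, while the KL term still regularizes the full posterior. With two
#'   independent per-view noise draws the invariance term saturates at its
#'   noise floor and the prior-collapsed solution becomes the attractor,
#'   which erases the mean structure the anomaly score depends on; see the
#'   package vignette.)
#' @return A `gca_config` list.
#' @export
gca_config <- function(lambda = 0.1, weights = c(1, 1, 1), lr = 1e-3,
                       epochs = 200, sample = FALSE) {
  stopifnot(lambda >= 0, length(weights) == 3, all(weights >= 0), lr >= 0, epochs >= 1)
  structure(list(lambda = lambda, weights = weights, lr = lr,
                 epochs = epochs, sample = sample), class = "gca_config")
}

#' Closed-form KL alignment loss
#'
#' Sum of KL divergences from each view's diagonal-Gaussian posterior to the
#' standard-normal prior, `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`,
#' summed over nodes and dimensions and over the views supplied. Minimizing
#' it pulls both views' distributions onto the same prior. Always >= 0.
#'
#' @param post_st Structural-view `gca_posterior`.
#' @param post_se Optional semantic-view `gca_posterior`; if supplied, the two
#'   views' divergences are added.
#' @return Scalar loss.
#' @export
kl_loss <- function(post_st, post_se = NULL) {
  one <- function(p) 0.5 * sum(p$mu^2 + exp(p$log_var) - 1 - p$log_var)
  out <- one(post_st)
  if (!is.null(post_se)) out <- out + one(post_se)
  out
}

#' Reconstruction loss
#'
#' Unsquared Frobenius norms: `||X - X_hat||_F + ||A - A_hat||_F`, the
#' attribute and structure reconstruction errors equally weighted.
#' @param X,X_hat N x D attribute matrices.
#' @param A,A_hat N x N structure matrices (raw adjacency vs its logistic
#'   reconstruction).
#' @return Scalar >= 0.
#' @export
recon_loss <- function(X, X_hat, A, A_hat) {
  if (!all(dim(X) == dim(X_hat))) stop("X / X_hat shape mismatch", call. = FALSE)
  if (!all(dim(A) == dim(A_hat))) stop("A / A_hat shape mismatch", call. = FALSE)
  frobenius(X - X_hat) + frobenius(A - A_hat)
}

#' Normalize embeddings for the soft-CCA comparison
#'
#' Per column: subtract the column mean, divide by the column standard
#' deviation (population convention, floored at an internal epsilon), and
#' divide by `sqrt(N)`. Under this scaling `t(Z') %*% Z'` is the column
#' correlation matrix, the object the decorrelation loss compares to the
#' identity.
#'
#' @param Z N x d embedding matrix, N >= 2.
#' @return Normalized matrix of the same shape.
#' @export
normalize_embeddings <- function(Z) {
  stop_if_not_matrix(Z, "Z")
  n <- nrow(Z)
  if (n < 2) stop("normalization needs at least 2 rows", call. = FALSE)
  m <- colMeans(Z)
  s <- sqrt(colMeans((Z - matrix(m, n, ncol(Z), byrow = TRUE))^2))
  s <- pmax(s, EPS)
  sweep(sweep(Z, 2, m, "-"), 2, s * sqrt(n), "/")
}

#' Invariance loss
#'
#' Squared Frobenius distance between the two normalized views,
#' `||Z_st' - Z_se'||_F^2`; zero iff the views agree exactly.
#' @param Zp_st,Zp_se Normalized embeddings ([normalize_embeddings]).
#' @return Scalar >= 0.
#' @export
invariance_loss <- function(Zp_st, Zp_se) {
  if (!all(dim(Zp_st) == dim(Zp_se))) stop("shape mismatch", call. = FALSE)
  sum((Zp_st - Zp_se)^2)
}

#' Decorrelation loss (one view)
#'
#' `||t(Z') %*% Z' - I||_F^2`: penalizes correlation between embedding
#' dimensions, preventing the collapsed solution where all dimensions carry
#' the same signal. Callers sum the two views.
#' @param Zp Normalized embedding.
#' @return Scalar >= 0.
#' @export
decorrelation_loss <- function(Zp) {
  stop_if_not_matrix(Zp, "Zp")
  C <- crossprod(Zp)
  sum((C - diag(ncol(Zp)))^2)
}

#' Assemble the total loss breakdown
#'
#' @param parts List with scalars `L_inv`, `L_dco`, `L_kl`, `L_dec`.
#' @param cfg A [gca_config].
#' @return A `gca_loss` breakdown: `L_inv`, `L_dco`, `L_CCA`, `L_kl`,
#'   `L_dec`, `L_total`, with `L_CCA = L_inv + lambda * L_dco` and
#'   `L_total` the weighted sum of `L_CCA`, `L_kl`, `L_dec`.
#' @export
total_loss <- function(parts, cfg = gca_config()) {
  L_CCA <- parts$L_inv + cfg$lambda * parts$L_dco
  w <- cfg$weights
  structure(list(
    L_inv = parts$L_inv, L_dco = parts$L_dco, L_CCA = L_CCA,
    L_kl = parts$L_kl, L_dec = parts$L_dec,
    L_total = w[1] * L_CCA + w[2] * parts$L_kl + w[3] * parts$L_dec
  ), class = "gca_loss")
}

# ---- full forward / backward over one clip ---------------------------------
#
# The analytic gradients below mirror the forward pass exactly; their
# correctness is pinned by a finite-difference check in the test suite.

# Precompute the per-clip constants the training step needs.
prep_instance <- function(graph) {
  P <- normalize_adjacency(graph$A)$A
  list(X = graph$X, P = P, PX = P %*% graph$X, A_raw = graph$A$A, N = nrow(graph$X))
}

view_forward <- function(inst, params, identity_view, E) {
  pre1 <- if (identity_view) inst$X %*% params$W1 else inst$PX %*% params$W1
  H <- relu(pre1)
  M <- if (identity_view) H else inst$P %*% H
  mu <- M %*% params$Wmu
  lv <- M %*% params$Wsig
  Z <- if (is.null(E)) mu else mu + exp(lv / 2) * E
  list(pre1 = pre1, H = H, M = M, mu = mu, lv = lv, Z = Z, E = E,
       identity_view = identity_view)
}

# Forward pass over both views of one clip; E_st/E_se are the reparameterization
# noise draws (NULL => use posterior means).
gca_forward <- function(inst, params, cfg, E_st = NULL, E_se = NULL) {
  st <- view_forward(inst, params, FALSE, E_st)
  se <- view_forward(inst, params, TRUE, E_se)
  Zf <- st$Z + se$Z
  dec <- decoder_forward(Zf, params)
  gram <- Zf %*% t(Zf)
  A_hat <- 1 / (1 + exp(-gram))
  Zp_st <- normalize_embeddings(st$Z)
  Zp_se <- normalize_embeddings(se$Z)
  parts <- list(
    L_inv = invariance_loss(Zp_st, Zp_se),
    L_dco = decorrelation_loss(Zp_st) + decorrelation_loss(Zp_se),
    L_kl = kl_loss(list(mu = st$mu, log_var = st$lv),
                   list(mu = se$mu, log_var = se$lv)),
    L_dec = recon_loss(inst$X, dec$X_hat, inst$A_raw, A_hat)
  )
  list(loss = total_loss(parts, cfg), st = st, se = se, Zf = Zf, dec = dec,
       A_hat = A_hat, Zp_st = Zp_st, Zp_se = Zp_se)
}

# Backprop the column z-score + 1/sqrt(N) normalization.
norm_backward <- function(G, Z) {
  n <- nrow(Z)
  m <- colMeans(Z)
  s <- pmax(sqrt(colMeans(sweep(Z, 2, m, "-")^2)), EPS)
  U <- sweep(sweep(Z, 2, m, "-"), 2, s, "/")
  gm <- colMeans(G)
  gu <- colMeans(G * U)
  core <- sweep(G, 2, gm, "-") - sweep(U, 2, gu, "*")
  sweep(core, 2, s * sqrt(n), "/")
}

view_backward <- function(v, inst, dZ, grads, w_kl) {
  dmu <- dZ + w_kl * v$mu
  dlv <- w_kl * 0.5 * (exp(v$lv) - 1)
  if (!is.null(v$E)) dlv <- dlv + dZ * v$E * exp(v$lv / 2) * 0.5
  grads$Wmu <- grads$Wmu + crossprod(v$M, dmu)
  grads$Wsig <- grads$Wsig + crossprod(v$M, dlv)
  dM <- dmu %*% t(grads$.params$Wmu) + dlv %*% t(grads$.params$Wsig)
  dH <- if (v$identity_view) dM else crossprod(inst$P, dM)
  dpre1 <- dH * (v$pre1 > 0)
  inp <- if (v$identity_view) inst$X else inst$PX
  grads$W1 <- grads$W1 + crossprod(inp, dpre1)
  grads
}

gca_backward <- function(fw, inst, params, cfg) {
  L <- params$dims$L
  w <- cfg$weights
  grads <- list(
    W1 = params$W1 * 0, Wmu = params$Wmu * 0, Wsig = params$Wsig * 0,
    Wd = lapply(params$Wd, function(m) m * 0),
    bd = lapply(params$bd, function(b) b * 0),
    .params = params
  )

  # reconstruction branch (unsquared Frobenius norms)
  rx <- fw$dec$X_hat - inst$X
  dXhat <- w[3] * rx / max(frobenius(rx), EPS)
  ra <- fw$A_hat - inst$A_raw
  dAhat <- w[3] * ra / max(frobenius(ra), EPS)

  dU <- dXhat
  dZf <- NULL
  for (l in rev(seq_len(L))) {
    grads$Wd[[l]] <- grads$Wd[[l]] + crossprod(fw$dec$Hs[[l]], dU)
    grads$bd[[l]] <- grads$bd[[l]] + colSums(dU)
    dHprev <- dU %*% t(params$Wd[[l]])
    if (l > 1) {
      dU <- dHprev * (fw$dec$Us[[l - 1]] > 0)
    } else {
      dZf <- dHprev
    }
  }
  dGram <- dAhat * fw$A_hat * (1 - fw$A_hat)
  dZf <- dZf + (dGram + t(dGram)) %*% fw$Zf

  # soft-CCA branch through the normalized views
  diffp <- fw$Zp_st - fw$Zp_se
  d <- ncol(fw$Zp_st)
  dZp_st <- w[1] * (2 * diffp + cfg$lambda * 4 * fw$Zp_st %*% (crossprod(fw$Zp_st) - diag(d)))
  dZp_se <- w[1] * (-2 * diffp + cfg$lambda * 4 * fw$Zp_se %*% (crossprod(fw$Zp_se) - diag(d)))

  dZ_st <- dZf + norm_backward(dZp_st, fw$st$Z)
  dZ_se <- dZf + norm_backward(dZp_se, fw$se$Z)

  grads <- view_backward(fw$st, inst, dZ_st, grads, w[2])
  grads <- view_backward(fw$se, inst, dZ_se, grads, w[2])
  grads$.params <- NULL
  grads
}

# flatten/unflatten param-shaped lists (used by Adam and the gradient check)
flatten_params <- function(p) {
  c(as.numeric(p$W1), as.numeric(p$Wmu), as.numeric(p$Wsig),
    unlist(lapply(p$Wd, as.numeric)), unlist(p$bd))
}

unflatten_params <- function(vec, template) {
  p <- template
  i <- 0
  take <- function(n) {
    out <- vec[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  p$W1 <- matrix(take(length(template$W1)), nrow(template$W1))
  p$Wmu <- matrix(take(length(template$Wmu)), nrow(template$Wmu))
  p$Wsig <- matrix(take(length(template$Wsig)), nrow(template$Wsig))
  p$Wd <- lapply(template$Wd, function(m) matrix(take(length(m)), nrow(m)))
  p$bd <- lapply(template$bd, function(b) take(length(b)))
  p
}

#' Total-loss gradient for one clip
#'
#' Analytic gradient of the total training loss with respect to every
#' parameter, with the reparameterization noise held fixed (so it can be
#' compared against finite differences). Exposed mainly for verification.
#'
#' @param graph An `eeg_graph`.
#' @param params `gca_params`.
#' @param cfg [gca_config].
#' @param E_st,E_se Fixed noise matrices (N x d) or `NULL` for posterior means.
#' @return List: `loss` (`gca_loss`) and `grads` (param-shaped list).
#' @export
gca_gradient <- function(graph, params, cfg = gca_config(), E_st = NULL, E_se = NULL) {
  inst <- prep_instance(graph)
  fw <- gca_forward(inst, params, cfg, E_st, E_se)
  list(loss = fw$loss, grads = gca_backward(fw, inst, params, cfg))
}

#' Train the detector on normal clips
#'
#' Minimizes the total objective with Adam, taking one full-batch gradient
#' step per clip per epoch (clips are independent training instances).
#' Deterministic given `seed`: initialization, reparameterization noise and
#' step order all come from one seeded stream.
#'
#' @param dataset List of `eeg_graph` objects (normal clips only).
#' @param cfg [gca_config].
#' @param params Optional initial `gca_params` (default: fresh Glorot init).
#' @param seed Integer seed.
#' @return List: `params` (trained), `history` (data.frame with one row per
#'   epoch: epoch, L_inv, L_dco, L_CCA, L_kl, L_dec, L_total, averaged over
#'   clips), `cfg`, `seed`.
#' @export
gca_train <- function(dataset, cfg = gca_config(), params = NULL, seed = 1) {
  stopifnot(length(dataset) >= 1)
  lapply(dataset, function(g) stopifnot(inherits(g, "eeg_graph")))
  N <- nrow(dataset[[1]]$X)
  if (!all(vapply(dataset, function(g) nrow(g$X), 0) == N)) {
    stop("all graphs must have the same channel count", call. = FALSE)
  }
  insts <- lapply(dataset, prep_instance)
  D <- ncol(dataset[[1]]$X)
  if (is.null(params)) params <- gca_params(D, seed = seed)
  d <- params$dims$d

  theta <- flatten_params(params)
  m_t <- v_t <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0
  hist <- matrix(0, cfg$epochs, 6,
                 dimnames = list(NULL, c("L_inv", "L_dco", "L_kl", "L_dec",
                                         "L_CCA", "L_total")))
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      acc <- numeric(6)
      for (ci in seq_along(insts)) {
        p_now <- unflatten_params(theta, params)
        E_st <- E_se <- NULL
        if (cfg$sample) {
          E_st <- matrix(stats::rnorm(N * d), N, d)
          E_se <- matrix(stats::rnorm(N * d), N, d)
        }
        fw <- gca_forward(insts[[ci]], p_now, cfg, E_st, E_se)
        if (!is.finite(fw$loss$L_total)) {
          bad <- names(Filter(function(x) !is.finite(x), unclass(fw$loss)))
          stop(sprintf("non-finite loss at epoch %d (term(s): %s)", ep,
                       paste(bad, collapse = ", ")), call. = FALSE)
        }
        g <- flatten_params(gca_backward(fw, insts[[ci]], p_now, cfg))
        t_step <- t_step + 1
        m_t <- b1 * m_t + (1 - b1) * g
        v_t <- b2 * v_t + (1 - b2) * g^2
        mhat <- m_t / (1 - b1^t_step)
        vhat <- v_t / (1 - b2^t_step)
        theta <- theta - cfg$lr * mhat / (sqrt(vhat) + adam_eps)
        acc <- acc + c(fw$loss$L_inv, fw$loss$L_dco, fw$loss$L_kl,
                       fw$loss$L_dec, fw$loss$L_CCA, fw$loss$L_total)
      }
      hist[ep, ] <- acc / length(insts)
    }
  })
  history <- data.frame(epoch = seq_len(cfg$epochs), hist)
  list(params = unflatten_params(theta, params), history = history,
       cfg = cfg, seed = seed)
}

#' Write the per-epoch loss history as CSV
#' @param history Data frame from [gca_train].
#' @param path Output path.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
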