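rand_posterior <- function(N = 3, d = 2, seed = 1) {
  set.seed(seed)
  structure(list(mu = matrix(rnorm(N * d), N),
                 log_var = matrix(rnorm(N * d, sd = 0.7), N)),
            class = "gca_posterior")
}

test_that("closed-form KL matches hand values and stays nonnegative", {
  prior <- structure(list(mu = matrix(0, 3, 2), log_var = matrix(0, 3, 2)),
                     class = "gca_posterior")
  expect_equal(kl_loss(prior), 0)
  expect_equal(kl_loss(prior, prior), 0)
  # single node, d = 1, mu = 1, sigma = 1: 0.5 * (1 + 1 - 1 - 0) = 0.5
  one <- structure(list(mu = matrix(1), log_var = matrix(0)),
                   class = "gca_posterior")
  expect_equal(kl_loss(one), 0.5)
  for (s in 1:10) expect_gte(kl_loss(rand_posterior(seed = s)), 0)
})

test_that("closed-form KL agrees with a Monte-Carlo estimate", {
  # KL[N(mu, s^2) || N(0,1)] estimated as mean of log q(z) - log p(z)
  for (s in 1:3) {
    post <- rand_posterior(N = 2, d = 2, seed = s)
    set.seed(100 + s)
    n <- 2e4
    mc <- 0
    for (i in seq_along(post$mu)) {
      sd_i <- exp(post$log_var[i] / 2)
      z <- rnorm(n, post$mu[i], sd_i)
      mc <- mc + mean(dnorm(z, post$mu[i], sd_i, log = TRUE) - dnorm(z, log = TRUE))
    }
    expect_equal(kl_loss(post), mc, tolerance = 0.05)
  }
})

test_that("reconstruction loss is the sum of unsquared Frobenius norms", {
  set.seed(2)
  X <- matrix(rnorm(12), 3); A <- matrix(runif(9), 3)
  expect_equal(recon_loss(X, X, A, A), 0)
  # A_hat = A + ones: Frobenius norm of the all-ones N x N matrix is N
  expect_equal(recon_loss(X, X, A, A + 1), 3)
  Xh <- X + rnorm(12); Ah <- A + rnorm(9)
  expect_equal(recon_loss(X, Xh, A, Ah),
               sqrt(sum((X - Xh)^2)) + sqrt(sum((A - Ah)^2)))
  expect_error(recon_loss(X, t(X), A, A), "mismatch")
})

test_that("embedding normalization produces a correlation-ready matrix", {
  set.seed(3)
  Z <- matrix(rnorm(40), 8, 5)
  Zp <- normalize_embeddings(Z)
  expect_true(all(abs(colMeans(Zp)) < 1e-10))
  expect_equal(unname(diag(crossprod(Zp))), rep(1, 5), tolerance = 1e-10)
  # an already-standardized column passes through as column / sqrt(N)
  v <- as.numeric(scale(rnorm(8))) * sqrt(8 / 7)  # population-sd standardized
  Zp2 <- normalize_embeddings(cbind(v, rnorm(8)))
  expect_equal(Zp2[, 1], v / sqrt(8), tolerance = 1e-10)
  expect_error(normalize_embeddings(matrix(1, 1, 2)), "2 rows")
})

test_that("invariance and decorrelation losses match their definitions", {
  set.seed(4)
  Z <- normalize_embeddings(matrix(rnorm(24), 6, 4))
  expect_equal(invariance_loss(Z, Z), 0)
  expect_equal(invariance_loss(Z, Z + 1), 24)  # squared Frobenius of ones
  expect_equal(invariance_loss(Z, Z + 2), invariance_loss(Z + 2, Z))

  # orthonormal-correlation columns: Q from a QR factorization
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  expect_equal(decorrelation_loss(Q), 0, tolerance = 1e-12)
  # two identical columns: off-diagonal pair contributes 1 + 1 = 2
  v <- rnorm(8)
  Zdup <- normalize_embeddings(cbind(v, v))
  expect_equal(decorrelation_loss(Zdup), 2, tolerance = 1e-10)
  Zr <- normalize_embeddings(matrix(rnorm(40), 8, 5))
  expect_equal(decorrelation_loss(Zr),
               sum((t(Zr) %*% Zr - diag(5))^2), tolerance = 1e-12)
})

test_that("total_loss assembles the breakdown per its invariants", {
  parts <- list(L_inv = 1, L_dco = 3, L_kl = 2, L_dec = 4)
  lb <- total_loss(parts, gca_config(lambda = 2))
  expect_equal(lb$L_CCA, 7)
  expect_equal(lb$L_total, 7 + 2 + 4)
  expect_equal(total_loss(parts, gca_config(lambda = 0))$L_CCA, parts$L_inv)
  zero <- total_loss(list(L_inv = 0, L_dco = 0, L_kl = 0, L_dec = 0), gca_config())
  expect_equal(zero$L_total, 0)
})

test_that("analytic gradients match finite differences on a tiny instance", {
  set.seed(9)
  X <- matrix(rnorm(4 * 5), 4, 5)
  g <- suppressWarnings(eeg_graph(build_corr_graph(X), X))
  p <- tiny_params(D = 5, d = 3)
  cfg <- gca_config(lambda = 0.3)
  E1 <- matrix(rnorm(12), 4, 3)
  E2 <- matrix(rnorm(12), 4, 3)
  res <- gca_gradient(g, p, cfg, E1, E2)
  ga <- eeggca:::flatten_params(res$grads)
  th <- eeggca:::flatten_params(p)
  f <- function(v) {
    gca_gradient(g, eeggca:::unflatten_params(v, p), cfg, E1, E2)$loss$L_total
  }
  h <- 1e-5
  gn <- vapply(seq_along(th), function(i) {
    e <- th; e[i] <- th[i] + h; up <- f(e)
    e[i] <- th[i] - h
    (up - f(e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-4)), 1e-4)
})

test_that("training is deterministic, inert at lr = 0, and reduces the loss", {
  graphs <- lapply(1:4, function(s) rand_graph_instance(N = 6, D = 5, seed = s))
  p0 <- tiny_params(D = 5)
  frozen <- gca_train(graphs, gca_config(lr = 0, epochs = 1), params = p0, seed = 3)
  expect_equal(frozen$params$W1, p0$W1)
  expect_equal(frozen$params$Wd[[1]], p0$Wd[[1]])

  fit1 <- gca_train(graphs, gca_config(epochs = 30, sample = TRUE), params = p0, seed = 3)
  fit2 <- gca_train(graphs, gca_config(epochs = 30, sample = TRUE), params = p0, seed = 3)
  expect_identical(fit1$params, fit2$params)
  expect_equal(nrow(fit1$history), 30)
  expect_lt(fit1$history$L_total[30], fit1$history$L_total[1])
  expect_true(all(is.finite(as.matrix(fit1$history))))

  # loss terms stay nonnegative along the whole trajectory
  expect_true(all(fit1$history$L_inv >= 0))
  expect_true(all(fit1$history$L_dco >= 0))
  expect_true(all(fit1$history$L_kl >= 0))
  expect_true(all(fit1$history$L_dec >= 0))
})
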