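test_that("the packaged 10-20 layout resolves labels and stays on the unit sphere", {
  lay <- standard_1020_layout()
  expect_equal(dim(lay$coords), c(19, 3))
  expect_true(all(abs(sqrt(rowSums(lay$coords^2)) - 1) < 0.01))
  cz <- standard_1020_layout("Cz")
  expect_equal(nrow(cz$coords), 1)
  expect_gt(cz$coords[1, 3], 0.99)  # vertex electrode points straight up
  expect_error(standard_1020_layout("Qz"), "unknown electrode")
})

test_that("spectral features peak at the synthesized frequency; degenerate channels are floored", {
  fs <- 128; n <- 256
  f <- 10                                 # bin index f * n / fs = 20
  t <- seq_len(n) / fs
  sig <- rbind(sin(2 * pi * f * t), rnorm(n))
  clip <- eeg_clip(sig, fs, c("s", "noise"))
  X <- extract_features(clip, "spectral", D = 40)
  expect_equal(unname(which.max(X[1, ])), f * n / fs)
  expect_equal(dim(X), c(2, 40))

  flat <- eeg_clip(rbind(rep(1, 64), rnorm(64)), 64, c("flat", "x"))
  expect_warning(Xr <- extract_features(flat, "raw", D = 16), "zero variance")
  expect_true(all(Xr[1, ] == 0))
  expect_error(extract_features(clip, "spectral", D = 200), "D <= samples/2")
})

test_that("distance graph follows the Gaussian-kernel/cutoff rule", {
  # coincident electrodes -> weight exp(0) = 1; separated beyond k -> 0
  V <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))
  lay <- structure(list(coords = V, labels = c("a", "b", "c")),
                   class = "electrode_layout")
  A <- build_dist_graph(lay, tau = 1, k = 0.9)$A
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 0)  # distance sqrt(2) > 0.9
  expect_error(build_dist_graph(lay, tau = -1), "tau")

  for (seed in 1:5) {
    set.seed(seed)
    V <- matrix(rnorm(19 * 3), 19, 3)
    V <- V / sqrt(rowSums(V^2))
    lay <- structure(list(coords = V, labels = sprintf("e%d", 1:19)),
                     class = "electrode_layout")
    A <- build_dist_graph(lay, tau = 0.7, k = 0.9)$A
    expect_equal(A, bf_dist_graph(V, 0.7, 0.9), tolerance = 1e-10)
    expect_equal(A, t(A))
  }
})

test_that("distance-graph weights are non-increasing in pairwise distance", {
  lay <- standard_1020_layout()
  A <- build_dist_graph(lay, tau = 1, k = 2)$A   # no cutoff censoring
  d <- as.matrix(dist(lay$coords))
  ut <- upper.tri(d)
  ord <- order(d[ut])
  expect_true(all(diff(A[ut][ord]) <= 1e-12))
})

test_that("correlation graph keeps each node's top-3 edges by |r|", {
  # a perfectly correlated pair always survives sparsification
  set.seed(3)
  X <- matrix(rnorm(8 * 16), 8, 16)
  X[2, ] <- 2 * X[1, ]
  A <- build_corr_graph(X)$A
  expect_equal(A[1, 2], 1, tolerance = 1e-10)

  set.seed(5)
  X19 <- matrix(rnorm(19 * 64), 19, 64)
  A19 <- build_corr_graph(X19)$A
  expect_true(all(rowSums(A19 != 0) <= 3))
  expect_true(all(diag(A19) == 0))

  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 16), 8, 16)
    expect_equal(build_corr_graph(X)$A, bf_corr_graph(X), tolerance = 1e-10)
  }
  expect_warning(build_corr_graph(matrix(rnorm(9), 3)), "too few channels")
})

test_that("rand/full/identity graphs match their closed forms", {
  expect_equal(build_rand_graph(3)$A,
               matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3))
  expect_equal(build_rand_graph(1)$A, matrix(1))
  for (N in c(2, 7, 19)) {
    expect_equal(rowSums(build_rand_graph(N)$A), rep(1 + 0.5 * (N - 1), N))
  }
  expect_equal(build_full_graph(2)$A, matrix(1, 2, 2))
  A <- build_full_graph(9)$A
  expect_equal(A, t(A))
  expect_equal(build_identity_graph(3)$A, diag(3))
  expect_equal(build_identity_graph(3)$kind, "identity")
})

test_that("transfer-function graph matches the double-loop oracle", {
  set.seed(6)
  X <- matrix(rnorm(19 * 64), 19, 64)
  A <- build_dtf_graph(X)$A
  expect_true(all(rowSums(A != 0) <= 3))
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 16), 6, 16)
    expect_equal(build_dtf_graph(X)$A, bf_dtf_graph(X), tolerance = 1e-10)
  }
  expect_error(build_dtf_graph(matrix(rnorm(8), 2)), ">= 3 channels")

  # a row orthogonal (after centering) to every other row has a zero row
  Xo <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1), c(1, 1, -1, -1))
  Ao <- suppressWarnings(build_dtf_graph(Xo))$A
  expect_equal(Ao[1, ], rep(0, 3), tolerance = 1e-12)
})

test_that("GCN normalization matches brute force and fixes degenerate cases", {
  # full graph without self-loops: every entry 1/N
  expect_equal(normalize_adjacency(build_full_graph(5), add_self_loops = FALSE)$A,
               matrix(1 / 5, 5, 5))
  idg <- build_identity_graph(4)
  expect_equal(normalize_adjacency(idg)$A, diag(4))
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(runif(64), 8, 8)
    A <- (A + t(A)) / 2
    got <- normalize_adjacency(A)
    expect_equal(got, bf_normalize(A), tolerance = 1e-12)
    expect_equal(got, t(got), tolerance = 1e-12)
  }
  expect_error(normalize_adjacency(matrix(0, 3, 3), add_self_loops = FALSE),
               "degree")
})

test_that("builders are deterministic", {
  set.seed(8)
  X <- matrix(rnorm(19 * 32), 19, 32)
  rownames(X) <- montage_1020_labels()
  for (kind in c("dist", "corr", "rand", "full", "dtf", "identity")) {
    expect_identical(build_graph(kind, X)$A, build_graph(kind, X)$A)
  }
})
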