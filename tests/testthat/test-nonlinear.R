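# PCA, kernel-ICA contrast and fit, base-signal projection

test_that("pca captures known variance structure", {
  # rank-2 data: two retained components explain everything
  set.seed(31)
  B <- matrix(rnorm(6), 3, 2)
  X <- matrix(rnorm(200), 100, 2) %*% t(B)
  m <- pca_fit(X, n_components = 2)
  expect_equal(m$cumulative_contribution, 1, tolerance = 1e-10)

  # 3-factor model: top eigenvalues match factor variances (oracle:
  # singular values of the centered data give the same spectrum)
  set.seed(32)
  F3 <- cbind(rnorm(1000, sd = 3), rnorm(1000, sd = 2), rnorm(1000, sd = 1))
  L <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))   # orthonormal loadings
  X3 <- F3 %*% t(L) + matrix(rnorm(1e5, sd = 1e-4), 1000, 100)
  suppressWarnings(m3 <- pca_fit(X3, n_components = 3))
  Xc <- sweep(X3, 2, colMeans(X3))
  oracle <- svd(Xc, nu = 0, nv = 0)$d[1:3]^2 / (nrow(X3) - 1)
  expect_equal(m3$eigenvalues[1:3], oracle, tolerance = 1e-8)
  expect_equal(m3$eigenvalues[1:3], c(9, 4, 1), tolerance = 0.2)

  # loadings orthonormal; completeness: full-rank reconstruction is exact
  expect_equal(crossprod(m$loadings), diag(2), tolerance = 1e-8)
  full <- pca_fit(X3[, 1:5], n_components = 5)
  sc <- pca_transform(X3[, 1:5], full)
  back <- sweep(sc %*% t(full$loadings), 2, full$mean_vector, "+")
  expect_lt(max(abs(back - X3[, 1:5])), 1e-8)

  expect_error(pca_fit(matrix(1, 10, 5), n_components = 2), "degenerate")
})

test_that("pca scores are centered with eigenvalue covariance", {
  set.seed(33)
  X <- matrix(rnorm(500), 100, 5) %*% diag(c(3, 2, 1.5, 1, 0.5))
  m <- pca_fit(X, n_components = 3)
  expect_equal(as.numeric(pca_transform(rbind(m$mean_vector), m)),
               numeric(3), tolerance = 1e-10)
  sc <- pca_transform(X, m)
  expect_equal(unname(cov(sc)), diag(m$eigenvalues[1:3]), tolerance = 1e-6)
  # reconstruction residual equals the discarded variance (direct oracle)
  back <- sc %*% t(m$loadings)
  Xc <- sweep(X, 2, m$mean_vector)
  expect_equal(sum((Xc - back)^2),
               (nrow(X) - 1) * sum(m$eigenvalues[4:5]), tolerance = 1e-6)
  expect_error(pca_transform(X[, 1:3], m), "mismatch")
})

test_that("rbf kernel and centered gram follow their definitions", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2)), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), 1), exp(-1), tolerance = 1e-12)
  d <- sapply(seq(0.5, 3, by = 0.5),
              function(r) rbf_kernel(0, r, 1))
  expect_true(all(diff(d) < 0))
  expect_error(rbf_kernel(0, 1, 0), "kernel_sigma")

  expect_lt(max(abs(centered_gram(rep(2, 5)))), 1e-12)
  G <- centered_gram(rnorm(50), 1)
  expect_lt(max(abs(rowSums(G))), 1e-8)

  # 3x3 case against explicit arithmetic
  s <- c(0, 1, 2)
  K <- outer(s, s, function(a, b) exp(-(a - b)^2 / 2))
  Kc <- K - matrix(rowMeans(K), 3, 3) -
    matrix(colMeans(K), 3, 3, byrow = TRUE) + mean(K)
  expect_equal(centered_gram(s, 1), Kc, tolerance = 1e-12)
})

test_that("kernel contrast separates independent from dependent sources", {
  set.seed(34)
  Z <- scale(cbind(runif(2000) - 0.5,
                   sign(rnorm(2000)) * abs(rnorm(2000))^1.5))
  c_ind <- kica_contrast(diag(2), Z)
  expect_gte(c_ind, 0)
  expect_lt(c_ind, 0.05)

  Zdup <- scale(cbind(Z[, 1], Z[, 1] + 1e-3 * rnorm(2000)))
  c_dup <- kica_contrast(diag(2), Zdup)
  expect_gt(c_dup, c_ind)
})

test_that("contrast is invariant to row permutation and sign flips", {
  set.seed(35)
  Z <- scale(matrix(rnorm(900), 300, 3))
  W <- qr.Q(qr(matrix(rnorm(9), 3)))
  base <- kica_contrast(W, Z)
  expect_equal(kica_contrast(W[c(3, 1, 2), ], Z), base, tolerance = 1e-6)
  expect_equal(kica_contrast(W * c(-1, 1, -1), Z), base, tolerance = 1e-6)
})

test_that("dense and low-rank contrast paths agree", {
  set.seed(36)
  Z <- scale(cbind(runif(400) - 0.5, rnorm(400)))
  a <- kica_contrast(diag(2), Z, method = "dense")
  b <- kica_contrast(diag(2), Z, method = "ichol")
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("kica recovers mixed non-Gaussian sources", {
  S3 <- make_nongaussian_sources(1000, seed = 37)
  set.seed(38)
  A <- matrix(rnorm(9), 3)
  m <- kica_fit(S3 %*% t(A), p = 3, seed = 5, n_restarts = 2, sweeps = 3)
  W_orig <- m$W %*% t(m$whitener$matrix)
  expect_lt(amari_index(W_orig, A), 0.1)
  expect_gte(m$contrast_value, 0)

  # already-independent input: the fit keeps a near-permutation
  m0 <- kica_fit(scale(S3), p = 3, seed = 5, n_restarts = 1, sweeps = 1)
  expect_lt(amari_index(m0$W %*% t(m0$whitener$matrix),
                        diag(apply(S3, 2, sd))), 0.1)

  # determinism under seed
  m2 <- kica_fit(S3 %*% t(A), p = 3, seed = 5, n_restarts = 2, sweeps = 3)
  expect_identical(m$W, m2$W)
})

test_that("whitening inside kica_fit produces unit covariance", {
  set.seed(39)
  X <- matrix(rnorm(2000), 500, 4) %*% matrix(rnorm(16), 4)
  m <- kica_fit(X, p = 4, seed = 1, n_restarts = 0, sweeps = 0)
  Z <- sweep(X, 2, m$whitener$mean) %*% m$whitener$matrix
  expect_equal(unname(cov(Z)), diag(4), tolerance = 1e-6)
})

test_that("base-signal projection is a pseudoinverse mapping", {
  set.seed(40)
  # orthogonal rows: projecting a base signal yields a unit vector
  S <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:4]
  S <- t(S)                                         # 4 x 10, orthonormal rows
  A <- project_beats(rbind(S[2, ]), S)
  expect_equal(as.numeric(A), c(0, 1, 0, 0), tolerance = 1e-8)
  expect_equal(as.numeric(project_beats(rbind(rep(0, 10)), S)),
               numeric(4))

  # least-squares property: residual orthogonal to every base signal
  S2 <- matrix(rnorm(40), 4, 10)
  x <- rnorm(10)
  co <- project_beats(rbind(x), S2)
  resid <- x - as.numeric(co %*% S2)
  expect_lt(max(abs(S2 %*% resid)), 1e-8)
  expect_error(project_beats(rbind(rnorm(7)), S2), "differ")

  # contract: n beats in, p coefficients out
  expect_equal(dim(project_beats(matrix(rnorm(1800 * 10), 1800), S2)),
               c(1800L, 4L))
})

test_that("pipeline of pca, kica and projection recovers mixing weights", {
  # beats built as mixtures of 4 localized base signals whose weights are
  # drawn from four distinctly non-Gaussian distributions (uniform,
  # heavy-tailed, bimodal, double-exponential) — the regime the kernel
  # contrast is designed for
  set.seed(41)
  n <- 600
  t <- 0:249
  bases <- sapply(c(40, 110, 170, 220), function(mu) exp(-(t - mu)^2 / 128))
  truth <- cbind(runif(n, 0.5, 1.5),
                 sign(rnorm(n)) * abs(rnorm(n))^2,
                 sample(c(-1, 1), n, TRUE) + 0.3 * rnorm(n),
                 sign(rnorm(n)) * rexp(n))
  X <- truth %*% t(bases)
  suppressWarnings(pca <- pca_fit(X, n_components = 4))
  m <- kica_fit(pca_transform(X, pca), p = 4, seed = 2, sweeps = 2,
                pca = pca)
  expect_equal(dim(m$S), c(4L, 250L))
  co <- project_beats(X, m$S)
  expect_true(all(matched_abs_correlations(co, truth) > 0.95))
  expect_equal(nrow(co), n)
})
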