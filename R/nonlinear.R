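# Nonlinear feature extraction: PCA reduction of beat matrices followed by
# kernel independent component analysis (KICA). The KICA independence
# measure is the kernel canonical-correlation contrast
# C(W) = -0.5 * log(lambda_M), where lambda_M is the smallest eigenvalue of
# the regularized correlation matrix assembled from centered Gram matrices
# of the estimated sources. Per-beat nonlinear features are the projection
# coefficients of each beat onto the recovered base-signal subspace.

#' Fit a principal component model
#'
#' Eigendecomposition of the sample covariance of column-centered data.
#' Retains a fixed number of leading components and records the achieved
#' cumulative contribution (fraction of total variance).
#'
#' @param X n x d numeric matrix (rows = observations).
#' @param contribution_target Desired cumulative contribution (default
#'   0.998); a warning is raised if the retained components fall short.
#' @param n_components Number of components to retain (default 20).
#' @return Object of class `pca_model`: `eigenvalues` (all, decreasing),
#'   `loadings` (d x n_components orthonormal), `n_components`,
#'   `cumulative_contribution`, `mean_vector`.
#' @export
pca_fit <- function(X, contribution_target = 0.998, n_components = 20L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 observations")
  if (n_components > d) stop("n_components exceeds data dimension")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (n - 1)
  if (all(abs(C) < .Machine$double.eps)) stop("degenerate all-constant data")
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  r <- sum(vals > vals[1] * 1e-12)
  if (n_components > r) {
    warning("n_components (", n_components, ") exceeds data rank (", r, ")")
  }
  cumcontrib <- sum(vals[seq_len(n_components)]) / sum(vals)
  if (cumcontrib < contribution_target) {
    warning(sprintf(
      "retained components reach %.4f cumulative contribution (< %.4f target)",
      cumcontrib, contribution_target))
  }
  structure(list(eigenvalues = vals,
                 loadings = eg$vectors[, seq_len(n_components), drop = FALSE],
                 n_components = as.integer(n_components),
                 cumulative_contribution = cumcontrib,
                 mean_vector = mu),
            class = "pca_model")
}

#' Project data onto a fitted principal component basis
#'
#' @param X n x d matrix with the same columns as the training data.
#' @param model A [pca_fit()] result.
#' @return n x n_components score matrix.
#' @export
pca_transform <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean_vector)) stop("dimension mismatch")
  sweep(X, 2, model$mean_vector) %*% model$loadings
}

#' Gaussian radial basis kernel
#'
#' @param u,v Numeric vectors of equal length.
#' @param kernel_sigma Kernel width (> 0).
#' @return `exp(-||u - v||^2 / (2 * kernel_sigma^2))`.
#' @export
rbf_kernel <- function(u, v, kernel_sigma = 1) {
  if (length(u) != length(v)) stop("dimension mismatch")
  if (kernel_sigma <= 0) stop("kernel_sigma must be > 0")
  exp(-sum((u - v)^2) / (2 * kernel_sigma^2))
}

#' Doubly-centered RBF Gram matrix of a scalar sample
#'
#' @param s Numeric vector of component samples (length n >= 2).
#' @param kernel_sigma Kernel width.
#' @return n x n symmetric matrix with (numerically) zero row sums.
#' @export
centered_gram <- function(s, kernel_sigma = 1) {
  s <- as.numeric(s)
  n <- length(s)
  if (n < 2) stop("need at least 2 samples")
  K <- exp(-outer(s, s, "-")^2 / (2 * kernel_sigma^2))
  H <- diag(n) - 1 / n
  H %*% K %*% H
}

# Incomplete Cholesky of the (uncentered) RBF Gram of a scalar sample with
# pivoting; stops when the residual trace drops below tol. K ~ G G'.
.ichol_rbf <- function(s, kernel_sigma, tol) {
  n <- length(s)
  d <- rep(1, n)                      # RBF diagonal
  G <- matrix(0, n, 0)
  inv2s2 <- 1 / (2 * kernel_sigma^2)
  while (sum(d) > tol && ncol(G) < n) {
    j <- which.max(d)
    col_k <- exp(-(s - s[j])^2 * inv2s2)
    if (ncol(G) > 0) col_k <- col_k - G %*% G[j, ]
    piv <- sqrt(max(d[j], .Machine$double.eps))
    g <- as.numeric(col_k) / piv
    G <- cbind(G, g)
    d <- pmax(d - g^2, 0)
  }
  unname(G)
}

# Per-component factor of the regularized correlation construction:
# eigenvectors U (n x m) and shrinkage weights r = lambda/(lambda + c) of
# the centered Gram, where c = n * kap / 2.
.kica_factor <- function(s, kap, kernel_sigma, method) {
  n <- length(s)
  cc <- n * kap / 2
  if (method == "dense") {
    K <- centered_gram(s, kernel_sigma)
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- eg$values > max(eg$values[1], 0) * 1e-12 & eg$values > 0
    if (!any(keep)) keep[1] <- TRUE
    U <- eg$vectors[, keep, drop = FALSE]
    lam <- pmax(eg$values[keep], 0)
  } else {
    G <- .ichol_rbf(s, kernel_sigma, tol = 1e-4 * n)
    Gc <- sweep(G, 2, colMeans(G))     # centering: H G
    sv <- svd(Gc, nu = min(dim(Gc)), nv = 0)
    keep <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8
    if (!any(keep)) keep[1] <- TRUE
    U <- sv$u[, keep, drop = FALSE]
    lam <- sv$d[keep]^2
  }
  list(U = U, r = lam / (lam + cc))
}

# Assemble the compact regularized correlation matrix from component
# factors and return its smallest eigenvalue.
.kica_lambda_min <- function(factors) {
  p <- length(factors)
  dims <- vapply(factors, function(f) ncol(f$U), 1L)
  off <- c(0L, cumsum(dims))
  total <- off[p + 1L]
  R <- diag(total)
  for (i in seq_len(p - 1L)) {
    Ui <- factors[[i]]$U * rep(factors[[i]]$r, each = nrow(factors[[i]]$U))
    for (j in (i + 1L):p) {
      Uj <- factors[[j]]$U * rep(factors[[j]]$r,
                                 each = nrow(factors[[j]]$U))
      B <- crossprod(Ui, Uj)
      R[(off[i] + 1L):off[i + 1L], (off[j] + 1L):off[j + 1L]] <- B
      R[(off[j] + 1L):off[j + 1L], (off[i] + 1L):off[i + 1L]] <- t(B)
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min(max(min(ev), .Machine$double.eps), 1)
}

#' Kernel canonical-correlation contrast of an unmixing matrix
#'
#' Estimates sources `Z %*% t(W)`, builds regularized centered RBF Gram
#' factors per source, assembles the compact correlation matrix and
#' returns `-0.5 * log(lambda_M)` for its smallest eigenvalue. Zero means
#' (kernel-measured) pairwise independence; the contrast is always >= 0.
#'
#' @param W p x p unmixing matrix (rows applied to whitened data).
#' @param Z n x p whitened data matrix.
#' @param kap Regularization (ridge enters as `n * kap / 2`; default 0.02).
#' @param kernel_sigma RBF width (default 1).
#' @param method `"auto"` (dense for n <= 500, incomplete Cholesky
#'   otherwise), `"dense"`, or `"ichol"`.
#' @return Non-negative contrast value.
#' @export
kica_contrast <- function(W, Z, kap = 0.02, kernel_sigma = 1,
                          method = c("auto", "dense", "ichol")) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (n < p || p < 2) stop("need n >= p >= 2")
  if (method == "auto") method <- if (n <= 500) "dense" else "ichol"
  S <- Z %*% t(W)
  factors <- lapply(seq_len(p), function(i) {
    .kica_factor(S[, i], kap, kernel_sigma, method)
  })
  -0.5 * log(.kica_lambda_min(factors))
}

# pairwise Jacobi rotations maximizing the sum of squared excess kurtoses
# over a fine angle grid; cheap, deterministic initializer for the
# kernel-contrast search
.kurtosis_jacobi <- function(Z, sweeps = 4L, grid = 64L) {
  p <- ncol(Z); n <- nrow(Z)
  W <- diag(p)
  Y <- Z
  thetas <- seq(-pi / 4, pi / 4, length.out = grid)
  kurt2 <- function(u, v) {
    ku <- mean(u^4) / mean(u^2)^2 - 3
    kv <- mean(v^4) / mean(v^2)^2 - 3
    ku^2 + kv^2
  }
  for (s in seq_len(sweeps)) {
    moved <- FALSE
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      u <- Y[, i]; v <- Y[, j]
      vals <- vapply(thetas, function(th) {
        kurt2(cos(th) * u + sin(th) * v, -sin(th) * u + cos(th) * v)
      }, numeric(1))
      k <- which.max(vals)
      if (vals[k] > kurt2(u, v) + 1e-12) {
        th <- thetas[k]
        Y[, i] <- cos(th) * u + sin(th) * v
        Y[, j] <- -sin(th) * u + cos(th) * v
        Wi <- cos(th) * W[i, ] + sin(th) * W[j, ]
        Wj <- -sin(th) * W[i, ] + cos(th) * W[j, ]
        W[i, ] <- Wi; W[j, ] <- Wj
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  W
}

.random_orthonormal <- function(p) {
  qr_d <- qr(matrix(stats::rnorm(p * p), p))
  Q <- qr.Q(qr_d)
  Q * sign(diag(qr.R(qr_d)))[col(Q)]
}

.givens_rotate <- function(W, i, j, theta) {
  cs <- cos(theta); sn <- sin(theta)
  Wi <- cs * W[i, ] + sn * W[j, ]
  Wj <- -sn * W[i, ] + cs * W[j, ]
  W[i, ] <- Wi; W[j, ] <- Wj
  W
}

#' Fit a kernel ICA model
#'
#' Whitens the input, selects the best starting rotation among the
#' identity, a fourth-order-cumulant Jacobi solution and seeded random
#' orthonormal restarts (all scored by [kica_contrast()]), then refines it
#' by Givens coordinate descent on the kernel contrast: for each component
#' pair a small grid of rotation angles is evaluated and the best
#' improving angle kept.
#'
#' @param X20 n x p input matrix (typically PCA scores).
#' @param p Number of sources (default: all columns).
#' @param kap Regularization (default 0.02).
#' @param kernel_sigma RBF width (default 1).
#' @param seed Integer seed controlling the random restarts.
#' @param n_restarts Random restart count (default 2).
#' @param sweeps Givens refinement sweeps over all pairs (default 2; 0
#'   keeps the best starting candidate).
#' @param angles Candidate rotation angles per pair.
#' @param method Contrast evaluation path passed to [kica_contrast()].
#' @param pca Optional [pca_fit()] model used to back-project the base
#'   signals into the original beat space.
#' @return Object of class `kica_model`: `W` (p x p unmixing, unit-norm
#'   rows), `whitener` (`mean`, `matrix`), `S` (p x d base-signal matrix;
#'   d = 250-sample beat space when `pca` is given, else the input space),
#'   `kap`, `kernel_sigma`, `p`, `contrast_value`, `converged`.
#' @export
kica_fit <- function(X20, p = ncol(X20), kap = 0.02, kernel_sigma = 1,
                     seed = 1L, n_restarts = 2L, sweeps = 2L,
                     angles = c(-pi / 6, -pi / 12, pi / 12, pi / 6),
                     method = c("auto", "dense", "ichol"), pca = NULL) {
  method <- match.arg(method)
  X20 <- as.matrix(X20)
  n <- nrow(X20)
  if (n <= p) stop("need more observations than sources")
  mu <- colMeans(X20)
  Xc <- sweep(X20, 2, mu)
  eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  if (any(eg$values[seq_len(p)] <= 0)) {
    stop("input has rank < p; reduce the number of sources")
  }
  Wh <- eg$vectors[, seq_len(p), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(p)]), p)
  Z <- Xc %*% Wh                                     # n x p, unit covariance
  obj <- function(W) kica_contrast(W, Z, kap, kernel_sigma, method)

  set.seed(as.integer(seed))
  candidates <- c(list(diag(p), .kurtosis_jacobi(Z)),
                  replicate(n_restarts, .random_orthonormal(p),
                            simplify = FALSE))
  scores <- vapply(candidates, obj, numeric(1))

  # Givens coordinate descent from one starting point: per pair, a grid
  # over the candidate angles followed by two narrowing passes
  refine <- function(W, best) {
    for (s in seq_len(sweeps)) {
      improved <- FALSE
      for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
        span_angles <- angles
        pair_best <- best; pair_theta <- 0
        for (pass in 1:3) {
          trial <- vapply(span_angles,
                          function(th) obj(.givens_rotate(W, i, j, th)),
                          numeric(1))
          k <- which.min(trial)
          if (trial[k] < pair_best - 1e-10) {
            pair_best <- trial[k]; pair_theta <- span_angles[k]
          }
          step <- min(diff(sort(unique(c(span_angles, 0))))) / 2
          span_angles <- pair_theta + c(-step, step)
        }
        if (pair_best < best - 1e-10) {
          W <- .givens_rotate(W, i, j, pair_theta)
          best <- pair_best
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(W = W, best = best)
  }

  best_i <- which.min(scores)
  W <- candidates[[best_i]]
  best <- scores[best_i]
  if (sweeps > 0 && p >= 2) {
    # refine every starting point: descent basins differ, and the best
    # initial score does not always sit in the best basin
    for (ci in seq_along(candidates)) {
      r <- refine(candidates[[ci]], scores[ci])
      if (r$best < best) {
        W <- r$W
        best <- r$best
      }
    }
  }
  W <- W / sqrt(rowSums(W^2))

  # base signals: mixing directions of the recovered sources, expressed in
  # the input space (and through the PCA loadings if supplied)
  mix <- Wh %*% t(W)            # input-space columns, s = Wc' x
  # pseudo-inverse of the unmixing in input coords gives mixing columns
  A_in <- t(MASS::ginv(t(mix)))                      # d_in x p
  S <- t(A_in)                                       # p x d_in
  if (!is.null(pca)) S <- S %*% t(pca$loadings)      # p x 250
  structure(list(W = W, whitener = list(mean = mu, matrix = Wh),
                 S = S, kap = kap, kernel_sigma = kernel_sigma,
                 p = as.integer(p), contrast_value = best,
                 converged = TRUE),
            class = "kica_model")
}

#' @export
print.kica_model <- function(x, ...) {
  cat("KICA model:", x$p, "sources; contrast C(W) =",
      format(x$contrast_value, digits = 5), "\n")
  invisible(x)
}

#' Project beats onto a base-signal subspace
#'
#' Computes `A = X %*% pinv(S)`: each row of `A` holds the coefficients of
#' one beat in the base-signal subspace (least-squares representation).
#'
#' @param beats n x d numeric matrix or a `beat_matrix`.
#' @param S p x d base-signal matrix (rows = base signals).
#' @return n x p coefficient matrix.
#' @export
project_beats <- function(beats, S) {
  X <- if (inherits(beats, "beat_matrix")) beats$data else as.matrix(beats)
  if (ncol(X) != ncol(S)) stop("beat and base-signal dimensions differ")
  X %*% MASS::ginv(S)
}

#' Amari index between an estimated unmixing and the true mixing
#'
#' Permutation- and scale-invariant distance in [0, 1]; zero iff
#' `W %*% A` is a scaled permutation matrix.
#'
#' @param W Estimated p x p unmixing matrix.
#' @param A True p x p mixing matrix.
#' @return Amari index.
#' @export
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  p <- nrow(P)
  row_term <- sum(rowSums(P) / apply(P, 1, max) - 1)
  col_term <- sum(colSums(P) / apply(P, 2, max) - 1)
  (row_term + col_term) / (2 * p * (p - 1))
}
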