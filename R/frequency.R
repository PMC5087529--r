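# Frequency-domain features: four-level db2 wavelet decomposition per
# beat, band statistics (max, min, mean, population standard deviation of
# cd1..cd4 and ca4 -> 20 values), and Fisher linear discriminant reduction
# to 4 dimensions.

.band_order <- c("cd1", "cd2", "cd3", "cd4", "ca4")
.stat_order <- c("max", "min", "mean", "std")

#' Four-level db2 band decomposition of one beat
#'
#' @param beat Numeric vector (length >= 16).
#' @param mode Boundary handling (default `"symmetric"`, matching the
#'   denoising module).
#' @return Object of class `band_decomposition`: list with `ca4` and
#'   `cd1`..`cd4`.
#' @export
dwt_bands <- function(beat, mode = "symmetric") {
  beat <- as.numeric(beat)
  if (length(beat) < 16L) stop("beat must have at least 16 samples")
  d <- dwt_decompose(beat, levels = 4L, wavelet = "db2", mode = mode)
  structure(list(ca4 = d$approximation,
                 cd1 = d$details$d1, cd2 = d$details$d2,
                 cd3 = d$details$d3, cd4 = d$details$d4),
            class = "band_decomposition")
}

#' Band statistics of a wavelet decomposition
#'
#' Maximum, minimum, mean and population standard deviation (divisor n) of
#' each band, in the fixed order (cd1, cd2, cd3, cd4, ca4) x (max, min,
#' mean, std).
#'
#' @param bands A [dwt_bands()] result.
#' @return Named numeric vector of length 20.
#' @export
band_statistics <- function(bands) {
  stopifnot(inherits(bands, "band_decomposition"))
  out <- unlist(lapply(.band_order, function(b) {
    x <- bands[[b]]
    c(max(x), min(x), mean(x), sqrt(mean((x - mean(x))^2)))
  }))
  names(out) <- as.vector(outer(.stat_order, .band_order,
                                function(s, b) paste(b, s, sep = "_")))
  out
}

#' Band-statistic feature matrix for a set of beats
#'
#' @param beats `beat_matrix` or numeric matrix (rows = beats).
#' @param mode Boundary handling for the per-beat decomposition.
#' @return n x 20 matrix of band statistics.
#' @export
frequency_statistics <- function(beats, mode = "symmetric") {
  X <- if (inherits(beats, "beat_matrix")) beats$data else as.matrix(beats)
  t(apply(X, 1, function(row) band_statistics(dwt_bands(row, mode))))
}

#' Fit a Fisher linear discriminant model
#'
#' Maximizes between-class over within-class scatter. The within-class
#' scatter is ridge-regularized by `1e-6 * trace` when (numerically)
#' singular; eigenvalue ties are broken by input order.
#'
#' @param F n x d feature matrix.
#' @param labels Class symbols (>= 2 observations per class).
#' @param n_out Output dimension (default 4; at most `n_classes - 1`).
#' @return Object of class `lda_model`: `discriminant_directions` (d x
#'   n_out), `class_means`, `grand_mean`, `n_out`, `eigenvalues`.
#' @export
lda_fit <- function(F, labels, n_out = 4L) {
  F <- as.matrix(F)
  labels <- as.character(labels)
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (n_out > length(classes) - 1L) {
    stop("n_out must be <= number of classes - 1")
  }
  d <- ncol(F)
  grand <- colMeans(F)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  mus <- matrix(0, length(classes), d,
                dimnames = list(classes, colnames(F)))
  for (cl in classes) {
    Fi <- F[labels == cl, , drop = FALSE]
    mu <- colMeans(Fi)
    mus[cl, ] <- mu
    Xc <- sweep(Fi, 2, mu)
    Sw <- Sw + crossprod(Xc)
    dm <- mu - grand
    Sb <- Sb + nrow(Fi) * tcrossprod(dm)
  }
  if (rcond(Sw) < 1e-12) {
    Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / d, d)
  }
  # generalized eigenproblem Sb v = lambda Sw v via symmetric reduction
  R <- chol(Sw)
  M <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)),
                 transpose = TRUE)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- backsolve(R, eg$vectors[, seq_len(n_out), drop = FALSE])
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  structure(list(discriminant_directions = V,
                 class_means = mus, grand_mean = grand,
                 n_out = as.integer(n_out),
                 eigenvalues = eg$values[seq_len(n_out)]),
            class = "lda_model")
}

#' Project features onto fitted discriminant directions
#'
#' @param F n x d matrix with the training-data columns.
#' @param model A [lda_fit()] result.
#' @return n x n_out reduced feature matrix.
#' @export
lda_transform <- function(F, model) {
  F <- as.matrix(F)
  if (ncol(F) != nrow(model$discriminant_directions)) {
    stop("dimension mismatch")
  }
  sweep(F, 2, model$grand_mean) %*% model$discriminant_directions
}

#' Fisher criterion of a projection
#'
#' Ratio of between-class to within-class scatter traces after projecting
#' onto `V`; used to compare discriminant against random projections.
#'
#' @param F n x d feature matrix.
#' @param labels Class symbols.
#' @param V d x k projection matrix.
#' @return Scalar criterion (higher = better separated).
#' @export
fisher_criterion <- function(F, labels, V) {
  P <- as.matrix(F) %*% V
  labels <- as.character(labels)
  grand <- colMeans(P)
  sw <- 0; sb <- 0
  for (cl in unique(labels)) {
    Pi <- P[labels == cl, , drop = FALSE]
    mu <- colMeans(Pi)
    sw <- sw + sum(sweep(Pi, 2, mu)^2)
    sb <- sb + nrow(Pi) * sum((mu - grand)^2)
  }
  sb / sw
}
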