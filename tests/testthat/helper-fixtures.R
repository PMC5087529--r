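# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# A multi-beat synthetic record: `n_beats` concatenated template copies of
# one class, optionally contaminated with white + power-line noise.
make_record_signal <- function(class = "N", n_beats = 12, white_sigma = 0,
                               powerline_amp = 0, seed = 1,
                               sampling_rate = 360) {
  tpl <- beat_templates()
  clean <- rep(tpl[[class]]$waveform, n_beats)
  set.seed(seed)
  t <- seq_along(clean) - 1
  noisy <- clean +
    stats::rnorm(length(clean), 0, white_sigma) +
    powerline_amp * sin(2 * pi * 50 * t / sampling_rate +
                          stats::runif(1, 0, 2 * pi))
  list(clean = clean, noisy = noisy)
}

# Greedy column matching by absolute correlation; returns the per-column
# best |cor| after assignment (for permutation/scale-invariant recovery
# checks).
matched_abs_correlations <- function(est, truth) {
  C <- abs(stats::cor(est, truth))
  out <- numeric(ncol(truth))
  for (k in seq_len(ncol(truth))) {
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    out[k] <- C[ij[1], ij[2]]
    C[ij[1], ] <- -1
    C[, ij[2]] <- -1
  }
  out
}

# Reference confusion matrices for the five-class evaluation (rows =
# true class in order N, LBBB, RBBB, PVC, APC); used as metric inputs.
reference_cm_database <- function() {
  matrix(c(200, 0, 0, 0, 0,
           0, 198, 0, 2, 0,
           0, 0, 200, 0, 0,
           0, 5, 0, 195, 0,
           3, 0, 0, 1, 96),
         nrow = 5, byrow = TRUE,
         dimnames = list(true = c("N", "LBBB", "RBBB", "PVC", "APC"),
                         predicted = c("N", "LBBB", "RBBB", "PVC", "APC")))
}

reference_cm_platform <- function() {
  matrix(c(195, 2, 0, 1, 2,
           4, 194, 0, 2, 0,
           0, 0, 199, 1, 0,
           1, 8, 2, 189, 0,
           1, 0, 0, 0, 99),
         nrow = 5, byrow = TRUE,
         dimnames = list(true = c("N", "LBBB", "RBBB", "PVC", "APC"),
                         predicted = c("N", "LBBB", "RBBB", "PVC", "APC")))
}

# i.i.d. non-Gaussian source panel for blind-source-separation tests
make_nongaussian_sources <- function(n, seed) {
  set.seed(seed)
  cbind(stats::runif(n) - 0.5,
        sign(stats::rnorm(n)) * abs(stats::rnorm(n))^2,
        sample(c(-1, 1), n, TRUE) + 0.3 * stats::rnorm(n))
}
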