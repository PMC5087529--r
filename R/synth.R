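# Synthetic five-class heartbeat generator. Templates are piecewise
# Gaussian-bump syntheses of P-QRS-T morphology: wide QRS complexes for the
# ventricular / bundle-branch-block classes, an early ectopic P wave for
# atrial premature beats. The generator gives every downstream stage a
# deterministic, self-contained input.

BEAT_CLASSES <- c("N", "LBBB", "RBBB", "PVC", "APC")

.gauss_bumps <- function(t, bumps) {
  y <- numeric(length(t))
  for (i in seq_len(nrow(bumps))) {
    y <- y + bumps$amp[i] * exp(-(t - bumps$mu[i])^2 / (2 * bumps$sd[i]^2))
  }
  y
}

.template_bumps <- list(
  # columns: mu (sample index of bump centre, R peak at 100), sd (width in
  # samples), amp (mV)
  N = data.frame(
    mu  = c(55, 93, 100, 108, 160),
    sd  = c(8, 3, 4, 3.5, 14),
    amp = c(0.15, -0.12, 1.0, -0.2, 0.3)),
  LBBB = data.frame(
    mu  = c(55, 100, 116, 172),
    sd  = c(8, 9, 6, 16),
    amp = c(0.12, 0.9, 0.5, -0.3)),
  RBBB = data.frame(
    mu  = c(55, 95, 103, 113, 165),
    sd  = c(8, 3, 4, 5, 14),
    amp = c(0.12, 0.45, -0.45, 0.85, -0.18)),
  PVC = data.frame(
    mu  = c(100, 120, 178),
    sd  = c(12, 8, 18),
    amp = c(1.25, -0.55, -0.5)),
  APC = data.frame(
    mu  = c(36, 99, 105, 148),
    sd  = c(5, 3, 3, 10),
    amp = c(0.3, 0.75, -0.3, 0.2))
)

#' Synthetic beat templates for the five heartbeat classes
#'
#' Each template is a 250-sample P-QRS-T waveform built from Gaussian
#' bumps, with the R peak at sample 101 (0-based index 100). The five
#' morphologies are pairwise distinct (zero-lag correlation of z-scored
#' waveforms < 0.99).
#'
#' @param length Samples per beat (default 250).
#' @param jitter Named list of per-beat variation fractions used by
#'   [generate_beats()]: `amp` (multiplicative amplitude sd), `width`
#'   (multiplicative width sd), `latency` (additive shift sd, samples).
#'   Set all to 0 for deterministic template copies.
#' @return Named list of `beat_template` objects, one per class, each with
#'   `class_label`, `waveform`, `bumps` and `jitter_params`.
#' @export
beat_templates <- function(length = 250L,
                           jitter = list(amp = 0.05, width = 0.03,
                                         latency = 2)) {
  t <- seq_len(length) - 1
  out <- lapply(BEAT_CLASSES, function(cl) {
    bumps <- .template_bumps[[cl]]
    structure(list(class_label = cl,
                   waveform = .gauss_bumps(t, bumps),
                   bumps = bumps,
                   jitter_params = jitter),
              class = "beat_template")
  })
  names(out) <- BEAT_CLASSES
  out
}

#' Generate a labelled matrix of synthetic beats
#'
#' Draws `n_per_class` jittered instances of every class template. Each
#' beat perturbs the template's bump parameters with a common amplitude
#' factor, width factor and latency shift drawn from the seeded RNG, so
#' identical seeds give bitwise-identical output.
#'
#' @param n_per_class Beats per class (>= 1).
#' @param templates Output of [beat_templates()]; all five classes must be
#'   present.
#' @param seed Integer RNG seed.
#' @return A `beat_matrix`: list with `data` (n x 250 numeric matrix),
#'   `labels` (factor with the five class levels) and `source_ids`
#'   (character provenance tags).
#' @export
generate_beats <- function(n_per_class, templates = beat_templates(),
                           seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  missing_cls <- setdiff(BEAT_CLASSES, names(templates))
  if (length(missing_cls) > 0) {
    stop("missing template class(es): ", paste(missing_cls, collapse = ", "))
  }
  len <- length(templates[[1]]$waveform)
  t <- seq_len(len) - 1
  set.seed(as.integer(seed))
  n_total <- 5L * n_per_class
  data <- matrix(0, nrow = n_total, ncol = len)
  labels <- character(n_total)
  ids <- character(n_total)
  row <- 0L
  for (cl in BEAT_CLASSES) {
    tpl <- templates[[cl]]
    jp <- tpl$jitter_params
    for (i in seq_len(n_per_class)) {
      row <- row + 1L
      amp_f <- 1 + jp$amp * stats::rnorm(1)
      wid_f <- 1 + jp$width * stats::rnorm(1)
      shift <- jp$latency * stats::rnorm(1)
      b <- tpl$bumps
      b$mu <- b$mu + shift
      b$sd <- b$sd * wid_f
      b$amp <- b$amp * amp_f
      data[row, ] <- .gauss_bumps(t, b)
      labels[row] <- cl
      ids[row] <- sprintf("synth:%s:%d", cl, i)
    }
  }
  beat_matrix(data, labels, ids)
}

#' Construct a beat matrix
#'
#' The central exchange format of the pipeline: a numeric matrix of
#' fixed-length beat segments with per-beat class labels.
#'
#' @param data Numeric matrix, one row per beat.
#' @param labels Class symbols, one per row (subset of N, LBBB, RBBB,
#'   PVC, APC).
#' @param source_ids Optional provenance strings.
#' @return Object of class `beat_matrix`.
#' @export
beat_matrix <- function(data, labels, source_ids = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(labels)) {
    stop("labels length must match number of beat rows")
  }
  bad <- setdiff(unique(as.character(labels)), BEAT_CLASSES)
  if (length(bad) > 0) stop("unknown class label(s): ",
                            paste(bad, collapse = ", "))
  if (is.null(source_ids)) source_ids <- sprintf("beat:%d", seq_len(nrow(data)))
  structure(list(data = unname(data),
                 labels = factor(as.character(labels), levels = BEAT_CLASSES),
                 source_ids = as.character(source_ids)),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat("Beat matrix:", nrow(x$data), "beats x", ncol(x$data), "samples\n")
  print(table(x$labels))
  invisible(x)
}

#' Noise specification for synthetic contamination
#'
#' Additive white Gaussian noise (electromyographic interference) plus a
#' power-line sinusoid.
#'
#' @param white_sigma Standard deviation of the Gaussian component (>= 0).
#' @param powerline_amp Amplitude of the power-line sinusoid (>= 0).
#' @param powerline_freq Power-line frequency in Hz (default 50).
#' @param sampling_rate Sampling rate in Hz (default 360, the MIT-BIH
#'   convention); must exceed twice the power-line frequency.
#' @param seed Integer RNG seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(white_sigma = 0.05, powerline_amp = 0.1,
                       powerline_freq = 50, sampling_rate = 360,
                       seed = 1L) {
  if (white_sigma < 0) stop("white_sigma must be >= 0")
  if (powerline_amp < 0) stop("powerline_amp must be >= 0")
  if (sampling_rate <= 2 * powerline_freq) {
    stop("sampling_rate must exceed twice the power-line frequency")
  }
  structure(list(white_sigma = white_sigma, powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Contaminate beats with white and power-line noise
#'
#' Adds Gaussian noise and a power-line sinusoid with a per-beat random
#' phase (drawn from the seeded RNG, so the contamination is reproducible
#' but not phase-locked across beats).
#'
#' @param beats A `beat_matrix`.
#' @param spec A [noise_spec()].
#' @return A new `beat_matrix` with the same labels.
#' @export
add_noise <- function(beats, spec) {
  stopifnot(inherits(beats, "beat_matrix"), inherits(spec, "noise_spec"))
  set.seed(spec$seed)
  n <- nrow(beats$data)
  len <- ncol(beats$data)
  t <- seq_len(len) - 1
  out <- beats$data
  for (i in seq_len(n)) {
    phi <- stats::runif(1, 0, 2 * pi)
    pl <- spec$powerline_amp *
      sin(2 * pi * spec$powerline_freq * t / spec$sampling_rate + phi)
    wn <- if (spec$white_sigma > 0) stats::rnorm(len, 0, spec$white_sigma)
          else numeric(len)
    out[i, ] <- out[i, ] + pl + wn
  }
  beat_matrix(out, beats$labels, beats$source_ids)
}
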