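# Classification and evaluation: one-vs-one RBF support vector machine
# (libsvm via e1071), genetic-algorithm search over the penalty C and
# kernel width delta with stratified cross-validated accuracy as fitness,
# and the confusion-matrix performance metrics (sensitivity, specificity,
# positive predictivity, accuracy).

#' Train an RBF support vector machine
#'
#' One-vs-one multiclass scheme (the libsvm convention). Features are
#' used as given — standardize beforehand (see [standardizer()]).
#'
#' @param X n x d feature matrix.
#' @param labels Class symbols (>= 2 classes).
#' @param C Penalty factor in (0, 100].
#' @param delta RBF kernel width in (0, 1000]; libsvm's `gamma` is
#'   `1 / (2 * delta^2)`.
#' @return Object of class `svm_classifier` wrapping the fitted model.
#' @export
svm_train <- function(X, labels, C = 1, delta = 1) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels))
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  if (C <= 0 || C > 100) stop("C must lie in (0, 100]")
  if (delta <= 0 || delta > 1000) stop("delta must lie in (0, 1000]")
  fit <- e1071::svm(X, droplevels(labels), type = "C-classification",
                    kernel = "radial", cost = C,
                    gamma = 1 / (2 * delta^2), scale = FALSE)
  structure(list(fit = fit, C = C, delta = delta, d = ncol(X)),
            class = "svm_classifier")
}

#' Predict beat classes
#'
#' @param object An `svm_classifier`.
#' @param newdata n x d feature matrix (same columns as training).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.svm_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) stop("feature dimension mismatch")
  as.character(stats::predict(object$fit, newdata))
}

#' Per-column z-score standardizer
#'
#' Records training means and standard deviations; apply with
#' [standardize()]. Constant columns get unit scale.
#'
#' @param X Training feature matrix.
#' @return Object of class `standardizer`.
#' @export
standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  structure(list(mean = mu, sd = sd), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param X Feature matrix.
#' @param sc A [standardizer()].
#' @return Standardized matrix.
#' @export
standardize <- function(X, sc) {
  sweep(sweep(as.matrix(X), 2, sc$mean), 2, sc$sd, "/")
}

# seed-deterministic stratified fold assignment
.stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  assign <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("fold count exceeds smallest class size")
    }
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Cross-validated accuracy of an SVM configuration
#'
#' Stratified k-fold mean accuracy; fold assignment is derived from the
#' seed only, so the value is deterministic and invariant to row order
#' (folds are drawn per class on sorted class indices).
#'
#' @param X Feature matrix.
#' @param labels Class symbols.
#' @param C,delta SVM parameters (see [svm_train()]).
#' @param folds Fold count (default 5; must not exceed the smallest class
#'   size).
#' @param seed Fold-assignment seed.
#' @param fold_assign Optional explicit fold assignment (integer vector in
#'   `1:folds`, one entry per row) overriding the seeded stratified draw;
#'   the accuracy depends only on which rows share a fold, not on row
#'   order.
#' @return Mean validation accuracy in [0, 1].
#' @export
cv_fitness <- function(X, labels, C, delta, folds = 5L, seed = 1L,
                       fold_assign = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  assign <- if (is.null(fold_assign)) {
    .stratified_folds(labels, folds, seed)
  } else {
    as.integer(fold_assign)
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- assign != f
    model <- svm_train(X[tr, , drop = FALSE], labels[tr], C, delta)
    mean(stats::predict(model, X[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  mean(acc)
}

#' Genetic-algorithm configuration
#'
#' @param max_iteration Generations (default 200).
#' @param population Individuals per generation (default 20).
#' @param cv_folds Cross-validation folds of the fitness (default 5).
#' @param bits_per_gene Binary resolution per parameter (default 16).
#' @param crossover_rate Single-point crossover probability (default 0.7).
#' @param mutation_rate Per-bit flip probability (default 0.01).
#' @param elitism Count of best individuals copied unchanged (default 1).
#' @param seed RNG seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(max_iteration = 200L, population = 20L,
                      cv_folds = 5L, bits_per_gene = 16L,
                      crossover_rate = 0.7, mutation_rate = 0.01,
                      elitism = 1L, seed = 1L) {
  stopifnot(population >= 2, cv_folds >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(max_iteration = as.integer(max_iteration),
                 population = as.integer(population),
                 cv_folds = as.integer(cv_folds),
                 bits_per_gene = as.integer(bits_per_gene),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# decode a bit vector to (0, hi]: zero maps just above 0 to avoid
# degenerate kernels
.decode_gene <- function(bits, hi) {
  v <- sum(bits * 2^(rev(seq_along(bits)) - 1))
  hi * (v + 1) / 2^length(bits)
}

#' Genetic-algorithm search for SVM hyperparameters
#'
#' Binary-coded two-gene chromosomes (penalty C, kernel width delta)
#' decoded linearly into their ranges; fitness-proportional (roulette)
#' selection with elitism, single-point crossover and per-bit mutation.
#' Fitness is [cv_fitness()] (or a custom function for testing). The
#' elitist copy makes the best-fitness trace non-decreasing.
#'
#' @param X,labels Training features and classes (ignored when `fitness`
#'   is supplied).
#' @param ga A [ga_config()].
#' @param c_range,delta_range Upper bounds of the decoded ranges
#'   (half-open at zero), defaults 100 and 1000.
#' @param fitness Optional function `(C, delta) -> numeric` replacing the
#'   cross-validated accuracy.
#' @return List with `best_C`, `best_delta`, `best_fitness` and `trace`
#'   (per-generation best fitness).
#' @export
ga_optimize <- function(X = NULL, labels = NULL, ga = ga_config(),
                        c_range = 100, delta_range = 1000,
                        fitness = NULL) {
  if (is.null(fitness)) {
    if (is.null(X) || is.null(labels)) stop("supply data or a fitness function")
    Xm <- as.matrix(X); lab <- as.character(labels)
    cache <- new.env(parent = emptyenv())
    fitness <- function(C, delta) {
      key <- sprintf("%.12g_%.12g", C, delta)
      if (!is.null(cache[[key]])) return(cache[[key]])
      val <- cv_fitness(Xm, lab, C, delta, folds = ga$cv_folds,
                        seed = ga$seed)
      cache[[key]] <- val
      val
    }
  }
  b <- ga$bits_per_gene
  set.seed(ga$seed)
  pop <- matrix(stats::rbinom(ga$population * 2L * b, 1, 0.5),
                nrow = ga$population)
  evaluate <- function(pop) {
    apply(pop, 1, function(ch) {
      fitness(.decode_gene(ch[seq_len(b)], c_range),
              .decode_gene(ch[(b + 1L):(2L * b)], delta_range))
    })
  }
  fit <- evaluate(pop)
  trace <- numeric(ga$max_iteration)
  best_ch <- pop[which.max(fit), ]
  best_fit <- max(fit)
  for (gen in seq_len(ga$max_iteration)) {
    # fitness-proportional selection (shifted to be positive)
    w <- fit - min(fit) + 1e-9
    parents <- sample.int(ga$population, ga$population, replace = TRUE,
                          prob = w)
    newpop <- pop[parents, , drop = FALSE]
    # single-point crossover on consecutive pairs
    for (k in seq(1L, ga$population - 1L, by = 2L)) {
      if (stats::runif(1) < ga$crossover_rate) {
        cut <- sample.int(2L * b - 1L, 1L)
        tmp <- newpop[k, (cut + 1L):(2L * b)]
        newpop[k, (cut + 1L):(2L * b)] <- newpop[k + 1L, (cut + 1L):(2L * b)]
        newpop[k + 1L, (cut + 1L):(2L * b)] <- tmp
      }
    }
    # mutation
    flips <- matrix(stats::runif(length(newpop)) < ga$mutation_rate,
                    nrow = nrow(newpop))
    newpop[flips] <- 1L - newpop[flips]
    # elitism: reinsert the best-so-far chromosomes
    if (ga$elitism > 0L) {
      newpop[seq_len(ga$elitism), ] <-
        matrix(best_ch, nrow = ga$elitism, ncol = 2L * b, byrow = TRUE)
    }
    pop <- newpop
    fit <- evaluate(pop)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_ch <- pop[which.max(fit), ]
    }
    trace[gen] <- best_fit
  }
  list(best_C = .decode_gene(best_ch[seq_len(b)], c_range),
       best_delta = .decode_gene(best_ch[(b + 1L):(2L * b)], delta_range),
       best_fitness = best_fit,
       trace = trace)
}

#' Confusion matrix over the five beat classes
#'
#' Rows are true classes, columns predicted, in the fixed order N, LBBB,
#' RBBB, PVC, APC.
#'
#' @param true_labels,predicted_labels Equal-length class symbol vectors.
#' @return 5 x 5 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), BEAT_CLASSES)
  if (length(bad) > 0) stop("unknown label symbol(s): ",
                            paste(bad, collapse = ", "))
  cm <- table(factor(true_labels, levels = BEAT_CLASSES),
              factor(predicted_labels, levels = BEAT_CLASSES))
  structure(unclass(matrix(as.integer(cm), 5, 5,
                           dimnames = list(true = BEAT_CLASSES,
                                           predicted = BEAT_CLASSES))),
            class = "confusion_matrix")
}

#' Performance metrics from a confusion matrix
#'
#' Per class c with TP = cm[c, c], FN = row sum - TP, FP = column sum -
#' TP, TN = total - TP - FN - FP: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictivity `TP/(TP+FP)`; overall accuracy
#' `(N_T - N_E)/N_T`. All values are percentages; a metric with a zero
#' denominator is `NA`.
#'
#' @param cm 5 x 5 confusion matrix (rows = true classes).
#' @return Object of class `metrics_report`: `per_class` data frame with
#'   `Se`, `Sp`, `Pp`; `averages` (mean over classes); `accuracy`.
#' @export
beat_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(5, 5))) stop("expected a 5 x 5 confusion matrix")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  per <- data.frame(Se = numeric(5), Sp = numeric(5), Pp = numeric(5),
                    row.names = BEAT_CLASSES)
  for (k in 1:5) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    per$Se[k] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    per$Sp[k] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    per$Pp[k] <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  }
  n_err <- total - sum(diag(cm))
  structure(list(per_class = per,
                 averages = colMeans(per, na.rm = TRUE),
                 accuracy = 100 * (total - n_err) / total),
            class = "metrics_report")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(matrix(unclass(x), 5, 5,
               dimnames = list(true = BEAT_CLASSES,
                               predicted = BEAT_CLASSES)))
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(round(x$per_class, 2))
  cat(sprintf("Average: Se %.2f  Sp %.2f  Pp %.2f\n",
              x$averages["Se"], x$averages["Sp"], x$averages["Pp"]))
  cat(sprintf("Accuracy: %.2f%%\n", x$accuracy))
  invisible(x)
}
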