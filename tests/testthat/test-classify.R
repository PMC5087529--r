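# SVM training, cross-validated fitness, GA search and metrics

blob_centers <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      c(1, 1, 0), c(0, 1, 1))

make_blobs <- function(n_per, sep = 6, seed = 61) {
  set.seed(seed)
  X <- do.call(rbind, lapply(1:5, function(k) {
    matrix(rnorm(n_per * 3), n_per) + rep(1, n_per) %o% (sep * blob_centers[k, ])
  }))
  list(X = X, y = rep(c("N", "LBBB", "RBBB", "PVC", "APC"), each = n_per))
}

test_that("svm separates well-separated classes and is deterministic", {
  bl <- make_blobs(30)
  m <- svm_train(bl$X, bl$y, C = 10, delta = 2)
  expect_equal(mean(predict(m, bl$X) == bl$y), 1)

  m2 <- svm_train(bl$X, bl$y, C = 10, delta = 2)
  set.seed(62)
  Xnew <- bl$X + matrix(rnorm(length(bl$X), sd = 0.1), nrow(bl$X))
  expect_identical(predict(m, Xnew), predict(m2, Xnew))

  # predictions commute with row permutation
  perm <- sample(nrow(Xnew))
  expect_identical(predict(m, Xnew[perm, ]), predict(m, Xnew)[perm])

  expect_error(svm_train(bl$X, bl$y, C = 0), "C must")
  expect_error(svm_train(bl$X, bl$y, delta = 2000), "delta must")
  expect_error(svm_train(bl$X, rep("N", nrow(bl$X))), "2 classes")
  expect_error(predict(m, bl$X[, 1:2]), "mismatch")
})

test_that("kernel width controls what the machine can represent", {
  # XOR layout: solvable with a narrow RBF kernel, not with a very wide
  # (locally linear) one
  set.seed(63)
  n <- 50
  X <- rbind(matrix(rnorm(2 * n, sd = 0.3), ncol = 2) +
               rep(1, n) %o% c(1, 1),
             matrix(rnorm(2 * n, sd = 0.3), ncol = 2) +
               rep(1, n) %o% c(-1, -1),
             matrix(rnorm(2 * n, sd = 0.3), ncol = 2) +
               rep(1, n) %o% c(1, -1),
             matrix(rnorm(2 * n, sd = 0.3), ncol = 2) +
               rep(1, n) %o% c(-1, 1))
  y <- rep(c("N", "N", "PVC", "PVC"), each = n)
  narrow <- svm_train(X, y, C = 10, delta = 0.5)
  wide <- svm_train(X, y, C = 10, delta = 1000)
  expect_gt(mean(predict(narrow, X) == y), 0.95)
  expect_lt(mean(predict(wide, X) == y), 0.75)
})

test_that("cross-validated fitness sits at chance for random labels", {
  set.seed(64)
  X <- matrix(rnorm(100 * 4), 100)
  y <- rep(c("N", "LBBB", "RBBB", "PVC", "APC"), each = 20)
  accs <- vapply(1:6, function(s) {
    cv_fitness(X, sample(y), C = 5, delta = 1, seed = s)
  }, numeric(1))
  expect_equal(mean(accs), 0.2, tolerance = 0.05)

  # near-perfect data scores near 1
  bl <- make_blobs(20)
  expect_gt(cv_fitness(bl$X, bl$y, C = 10, delta = 2, seed = 1), 0.95)

  expect_error(cv_fitness(X[1:8, ], rep(c("N", "PVC"), 4), 1, 1, folds = 5),
               "exceeds")
})

test_that("fitness depends only on fold membership, not row order", {
  bl <- make_blobs(12, sep = 2.5)
  fa <- ecgmdfx:::.stratified_folds(bl$y, 5L, seed = 9L)
  base <- cv_fitness(bl$X, bl$y, C = 3, delta = 1.5, fold_assign = fa)
  set.seed(65)
  perm <- sample(length(bl$y))
  permuted <- cv_fitness(bl$X[perm, ], bl$y[perm], C = 3, delta = 1.5,
                         fold_assign = fa[perm])
  expect_equal(base, permuted, tolerance = 1e-12)
})

test_that("ga locates the optimum of an analytic fitness surface", {
  # scale the basin widths so a 2%-of-range error is clearly resolvable
  surrogate <- function(C, delta) {
    exp(-((C - 30) / 20)^2 - ((delta - 400) / 100)^2)
  }
  out <- ga_optimize(ga = ga_config(max_iteration = 100, population = 20,
                                    seed = 3),
                     fitness = surrogate)
  expect_lt(abs(out$best_C - 30), 2)        # within 2% of the C range
  expect_lt(abs(out$best_delta - 400), 20)  # within 2% of the delta range

  # elitism makes the best-fitness trace non-decreasing
  expect_true(all(diff(out$trace) >= 0))
  expect_equal(out$best_fitness, max(out$trace))

  # seed determinism
  out2 <- ga_optimize(ga = ga_config(max_iteration = 100, population = 20,
                                     seed = 3),
                      fitness = surrogate)
  expect_identical(out[c("best_C", "best_delta", "trace")],
                   out2[c("best_C", "best_delta", "trace")])

  expect_error(ga_optimize(ga = ga_config()), "supply data")
})

test_that("gene decoding covers the half-open range", {
  b <- 16L
  expect_equal(ecgmdfx:::.decode_gene(rep(1L, b), 100), 100)
  expect_gt(ecgmdfx:::.decode_gene(rep(0L, b), 100), 0)
  expect_equal(ecgmdfx:::.decode_gene(c(rep(0L, b - 1L), 1L), 100),
               2 * 100 / 2^b)
})

test_that("svm decisions agree with nearest centroid on gaussian blobs", {
  bl <- make_blobs(40, sep = 4)
  m <- svm_train(bl$X, bl$y, C = 10, delta = 3)
  set.seed(66)
  Xte <- do.call(rbind, lapply(1:5, function(k) {
    matrix(rnorm(40 * 3), 40) + rep(1, 40) %o% (4 * blob_centers[k, ])
  }))
  centroids <- rowsum(bl$X, bl$y) / 40
  nc <- rownames(centroids)[apply(Xte, 1, function(x) {
    which.min(colSums((t(centroids) - x)^2))
  })]
  expect_gt(mean(predict(m, Xte) == nc), 0.9)
})

test_that("confusion matrix counts by the fixed class order", {
  cm <- confusion_matrix(c("N", "N", "PVC", "APC"),
                         c("N", "PVC", "PVC", "APC"))
  expect_equal(rownames(cm), c("N", "LBBB", "RBBB", "PVC", "APC"))
  expect_equal(cm["N", "N"], 1L)
  expect_equal(cm["N", "PVC"], 1L)
  expect_equal(sum(cm), 4L)
  expect_error(confusion_matrix("N", c("N", "PVC")), "differ")
  expect_error(confusion_matrix("N", "Q"), "unknown")
})

test_that("metrics follow their defining formulas", {
  # perfect matrix
  perfect <- diag(c(10L, 10L, 10L, 10L, 10L))
  m <- beat_metrics(perfect)
  expect_equal(unname(unlist(m$per_class)), rep(100, 15))
  expect_equal(m$accuracy, 100)

  # hand-worked 3-error example (100 beats total): 2 N beats called PVC,
  # 1 PVC called APC
  cm <- diag(c(20L, 20L, 20L, 19L, 20L))
  cm[1, 4] <- 2L; cm[1, 1] <- 18L; cm[4, 5] <- 1L
  r <- beat_metrics(cm)
  expect_equal(r$per_class["N", "Se"], 100 * 18 / 20)
  expect_equal(r$per_class["PVC", "Se"], 100 * 19 / 20)
  expect_equal(r$per_class["PVC", "Pp"], 100 * 19 / 21)
  expect_equal(r$per_class["PVC", "Sp"], 100 * 78 / 80)  # TN 78, FP 2
  expect_equal(r$per_class["APC", "Pp"], 100 * 20 / 21)
  expect_equal(r$accuracy, 100 * 97 / 100)

  # dual form of accuracy
  expect_equal(r$accuracy, 100 * sum(diag(cm)) / sum(cm))

  # metrics commute with a joint row/column class permutation
  p <- c(3, 1, 5, 2, 4)
  rp <- beat_metrics(cm[p, p])
  expect_equal(unname(as.matrix(rp$per_class)),
               unname(as.matrix(r$per_class)[p, ]))
  expect_equal(rp$accuracy, r$accuracy)

  # absent class yields NA sensitivity, excluded from the average
  cm0 <- diag(c(10L, 10L, 10L, 10L, 0L))
  r0 <- beat_metrics(cm0)
  expect_true(is.na(r0$per_class["APC", "Se"]))
  expect_equal(unname(r0$averages["Se"]), 100)
  expect_error(beat_metrics(matrix(0L, 5, 5)), "empty")
  expect_error(beat_metrics(diag(3)), "5 x 5")
})

test_that("standardizer reproduces z-scores and handles constants", {
  set.seed(67)
  X <- cbind(rnorm(50, 5, 2), rnorm(50, -1, 0.5), rep(3, 50))
  sc <- standardizer(X)
  Z <- standardize(X, sc)
  expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-10)
  expect_true(all(Z[, 3] == 0))
})
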