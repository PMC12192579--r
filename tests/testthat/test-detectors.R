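test_that("Mahalanobis distances satisfy the definition and trace identity", {
  # 1-D: data (-1, 0, 1) has mean 0, sample variance 1, so D2(1) = 1
  d2 <- mahalanobis_d2(matrix(c(-1, 0, 1), 3))
  expect_equal(unname(d2[3]), 1)
  X <- withr::with_seed(10, matrix(rnorm(500), 100, 5))
  d2 <- mahalanobis_d2(X)
  expect_true(all(d2 >= 0))
  expect_equal(sum(d2), 5 * 99)  # sum D2 = p (N - 1)
  # a row at the original centroid scores (essentially) zero
  Y <- rbind(X, colMeans(X))
  expect_lt(mahalanobis_d2(Y)[101] / max(mahalanobis_d2(Y)), 1e-10)
})

test_that("Mahalanobis distances are invariant to invertible affine maps", {
  X <- withr::with_seed(11, matrix(rnorm(400), 80, 5))
  A <- withr::with_seed(12, matrix(rnorm(25), 5, 5)) + diag(5)
  b <- 1:5
  Y <- sweep(X %*% A, 2, b, "+")
  expect_equal(mahalanobis_d2(Y), mahalanobis_d2(X), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("singular covariance errors under solve and is handled by pseudo", {
  X <- withr::with_seed(13, matrix(rnorm(200), 50, 4))
  Xs <- cbind(X, X[, 1] + X[, 2], 7)   # collinear + constant column
  expect_error(mahalanobis_d2(Xs, "solve"), "pseudo")
  d2 <- mahalanobis_d2(Xs, "pseudo")
  expect_equal(attr(d2, "rank"), 4L)
  expect_equal(sum(d2), 4 * 49)        # trace identity at the effective rank
  # pseudo-inverse on full-rank data reproduces the plain solve
  expect_equal(as.numeric(mahalanobis_d2(X, "pseudo")),
               as.numeric(mahalanobis_d2(X, "solve")), tolerance = 1e-8)
  # the pseudo route is scale-equivariant
  Xr <- sweep(Xs, 2, c(1, 1e4, 1e-4, 1, 2, 1), "*")
  expect_equal(as.numeric(mahalanobis_d2(Xr, "pseudo")), as.numeric(d2),
               tolerance = 1e-6)
})

test_that("isolation forest isolates a distant point and is seed-deterministic", {
  X <- rbind(matrix(0, 200, 3) + withr::with_seed(1, matrix(rnorm(600, sd = 0.01), 200, 3)),
             c(50, 50, 50))
  s <- isolation_forest_scores(X, seed = 5)
  expect_equal(which.min(s), 201L)
  expect_identical(s, isolation_forest_scores(X, seed = 5))
  expect_false(identical(s, isolation_forest_scores(X, seed = 6)))
})

test_that("isolation forest ranks planted 10-sigma outliers at the top", {
  N <- 2000L
  X <- withr::with_seed(21, matrix(rnorm(N * 5), N, 5))
  planted <- withr::with_seed(22, sample(N, 20))
  X[planted, ] <- X[planted, ] + 10
  s <- isolation_forest_scores(X, seed = 23)
  cutoff <- sort(s)[ceiling(0.02 * N)]      # most-anomalous 2%
  expect_true(all(s[planted] <= cutoff))
})

test_that("systematic mini-batches partition rows by index modulo m", {
  expect_equal(plan_minibatches(18L, 18L), 1:18)
  a <- plan_minibatches(180L, 18L)
  expect_equal(as.integer(table(a)), rep(10L, 18))
  expect_equal(a, ((seq_len(180) - 1L) %% 18L) + 1L)
  expect_setequal(unique(a), 1:18)
  expect_error(plan_minibatches(10L, 18L), "batches")
})

test_that("one-class SVM flags a distant point and is deterministic", {
  X <- rbind(withr::with_seed(2, matrix(rnorm(300, sd = 0.05), 100, 3)),
             c(30, 30, 30))
  s <- ocsvm_scores(X)
  expect_equal(which.min(s), 101L)
  expect_identical(s, ocsvm_scores(X))
})

test_that("mini-batch SVM ranks planted outliers at the top and is equivariant", {
  N <- 600L
  X <- withr::with_seed(31, matrix(rnorm(N * 4), N, 4))
  planted <- withr::with_seed(32, sample(N, 6))
  X[planted, ] <- X[planted, ] + 10
  batches <- plan_minibatches(N, 2L)
  s <- ocsvm_scores(X, batches)
  cutoff <- sort(s)[ceiling(0.05 * N)]
  expect_true(all(s[planted] <= cutoff))
  # permuting rows (and the plan with them) permutes scores near-identically;
  # libsvm's working-set heuristics depend slightly on data order, so the
  # equivariance is numerical rather than bitwise
  perm <- withr::with_seed(33, sample(N))
  expect_equal(ocsvm_scores(X[perm, ], batches[perm]), s[perm],
               tolerance = 1e-3)
  expect_error(ocsvm_scores(X, rep(c(1L, 2L), c(N - 2L, 2L))), "min_batch")
})

test_that("score_anomalies wraps detectors with anchors and metadata", {
  s <- fake_stats(140, seed = 17)
  f <- moment_features(s, 129L)
  sc <- score_anomalies(f, "mahalanobis", cov_method = "pseudo")
  expect_equal(nrow(sc), 12L)
  expect_true(all(c("chrom", "center_position", "raw_score", "d2") %in% names(sc)))
  expect_equal(attr(sc, "detector"), "mahalanobis")
  expect_equal(attr(sc, "feature_set"), "moments")
  expect_gt(attr(sc, "dof"), 0L)
  expect_error(score_anomalies(f, "iforest"), "seed")
  sc2 <- score_anomalies(f, "iforest", seed = 1)
  expect_equal(attr(sc2, "dof"), 1L)
})
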