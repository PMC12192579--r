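test_that("stretch bookkeeping counts and anchors are correct", {
  s <- fake_stats(190)  # e.g. L = 240 SNPs, l = 51 -> 190 windows
  idx <- stretch_index(s, 129L)
  expect_equal(nrow(idx), 62L)             # 190 - 129 + 1
  expect_equal(idx$center_window, idx$stretch + 64L)  # 65th window anchors
  s1 <- fake_stats(129)
  expect_equal(nrow(stretch_index(s1, 129L)), 1L)
  expect_warning(idx0 <- stretch_index(fake_stats(100), 129L), "no stretches")
  expect_equal(nrow(idx0), 0L)
})

test_that("moment features have 32 columns and match a per-column oracle", {
  s <- fake_stats(140, seed = 11)
  f <- moment_features(s, stretch_size = 129L)
  cols <- attr(f, "feature_cols")
  expect_length(cols, 32L)
  expect_equal(nrow(f), 12L)
  # brute force: recompute each stretch column-wise with dist_moments
  stats_mat <- as.matrix(s[, c("mu", "sigma2", "gamma", "beta",
                               "f1", "f2", "f3", "f4")])
  for (i in c(1L, 7L, 12L)) {
    rows <- f$stretch[i]:(f$stretch[i] + 128L)
    oracle <- as.vector(apply(stats_mat[rows, ], 2L, dist_moments))
    expect_equal(unname(unlist(f[i, cols])), oracle, tolerance = 1e-12)
  }
  # constant stretch: variances, skews and kurtoses all zero
  s0 <- fake_stats(129)
  s0[, 4:11] <- lapply(s0[, 4:11], function(x) rep(x[1], length(x)))
  f0 <- moment_features(s0, 129L)
  expect_true(all(abs(unlist(f0[, grep("_(var|skew|kurt)$", names(f0))])) == 0))
})

test_that("the B-spline basis is a partition of unity with analytic derivatives", {
  b <- spline_basis(129L, n_basis = 10L)
  expect_equal(dim(b$Phi), c(129L, 10L))
  expect_equal(rowSums(b$Phi), rep(1, 129))
  expect_equal(rowSums(b$dPhi), rep(0, 129), tolerance = 1e-12)
  # second derivative agrees with centred finite differences of the first
  h <- 1e-4
  grid <- seq(5, 125, length.out = 41)
  d1 <- function(x) splines::splineDesign(b$knots, x, ord = 4L,
                                          derivs = rep(1L, length(x)))
  fd <- (d1(grid + h) - d1(grid - h)) / (2 * h)
  an <- splines::splineDesign(b$knots, grid, ord = 4L,
                              derivs = rep(2L, length(grid)))
  expect_equal(fd, an, tolerance = 1e-6)
  expect_error(spline_basis(129L, n_basis = 3L), "order")
})

test_that("least-squares coefficients reproduce in-space curves exactly", {
  b <- spline_basis(129L, n_basis = 10L)
  t <- seq_len(129)
  # constants lie in the spline space
  cc <- fit_basis_coef(rep(2.5, 129), b)
  expect_equal(drop(b$Phi %*% cc), rep(2.5, 129), tolerance = 1e-10)
  # cubics lie in the cubic spline space
  y <- (t / 50)^3
  cy <- fit_basis_coef(y, b)
  expect_equal(drop(b$Phi %*% cy), y, tolerance = 1e-9)
  # exact recovery of in-space coefficients
  cstar <- withr::with_seed(4, rnorm(10))
  expect_equal(fit_basis_coef(drop(b$Phi %*% cstar), b), cstar,
               tolerance = 1e-9)
})

test_that("derivative features vanish for constants/linears and track t^2", {
  b <- spline_basis(129L)
  t <- seq_len(129)
  c_const <- fit_basis_coef(rep(1, 129), b)
  expect_equal(derivative_coef(c_const, b, 1L), rep(0, 10), tolerance = 1e-10)
  c_lin <- fit_basis_coef(2 + 0.3 * t, b)
  expect_equal(derivative_coef(c_lin, b, 2L), rep(0, 10), tolerance = 1e-8)
  # f(t) = (t/10)^2 has f'(t) = t/50, recoverable from the re-fit coefficients
  c_sq <- fit_basis_coef((t / 10)^2, b)
  d1 <- derivative_coef(c_sq, b, 1L)
  expect_equal(drop(b$Phi %*% d1), t / 50, tolerance = 1e-8)
  expect_error(derivative_coef(c_sq, b, 3L), "1 or 2")
})

test_that("FDA features have 240 columns, are linear, and recover in-space curves", {
  s <- fake_stats(140, seed = 13)
  f <- fda_features(s, stretch_size = 129L, n_basis = 10L)
  expect_length(attr(f, "feature_cols"), 240L)
  expect_equal(nrow(f), 12L)
  # linearity: scaling the statistics scales every feature block
  s2 <- s
  s2[, 4:11] <- lapply(s2[, 4:11], function(x) 3 * x)
  f2 <- fda_features(s2, 129L, 10L)
  cols <- attr(f, "feature_cols")
  expect_equal(as.matrix(f2[cols]), 3 * as.matrix(f[cols]), tolerance = 1e-9)
  # constant stretch: only the fit blocks are nonzero
  s0 <- fake_stats(129)
  s0[, 4:11] <- lapply(s0[, 4:11], function(x) rep(x[1], length(x)))
  f0 <- fda_features(s0, 129L, 10L)
  expect_true(all(abs(unlist(f0[, grep("_(d1|d2)", names(f0))])) < 1e-8))
  # in-space curves: the fit block equals the generating coefficients
  b <- spline_basis(129L)
  cstar <- withr::with_seed(8, rnorm(10))
  s1 <- fake_stats(129)
  s1$mu <- drop(b$Phi %*% cstar)
  f1 <- fda_features(s1, 129L, 10L, basis = b)
  expect_equal(unname(unlist(f1[, paste0("mu_fit", sprintf("%02d", 1:10))])),
               cstar, tolerance = 1e-9)
})

test_that("reconstruction error is non-increasing in the basis dimension", {
  y <- withr::with_seed(3, cumsum(rnorm(129)))
  err <- vapply(c(4L, 6L, 10L), function(B) {
    b <- spline_basis(129L, n_basis = B)
    sqrt(sum((y - drop(b$Phi %*% fit_basis_coef(y, b)))^2))
  }, 0)
  expect_true(all(diff(err) <= 1e-9))
})

test_that("feature assembly concatenates chromosomes with bookkeeping intact", {
  sa <- fake_stats(133, seed = 1, chrom = "1")   # 5 stretches at w = 129
  sb <- fake_stats(135, seed = 2, chrom = "2")   # 7 stretches
  fa <- moment_features(sa, 129L)
  fb <- moment_features(sb, 129L)
  f <- assemble_features(list(fa, fb))
  expect_equal(nrow(f), 12L)
  expect_equal(f$chrom, c(rep("1", 5), rep("2", 7)))
  expect_equal(f$center_position,
               c(fa$center_position, fb$center_position))
  # multi-chromosome stats input takes the same path
  f_joint <- moment_features(dplyr::bind_rows(sa, sb), 129L)
  expect_equal(f_joint, f, ignore_attr = TRUE)
  expect_error(assemble_features(list(fa, fda_features(sb, 129L))), "mix")
})
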