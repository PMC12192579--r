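#' Squared Mahalanobis distance of each row from the sample centroid
#'
#' `D2_i = (x_i - xbar)' C^{-1} (x_i - xbar)` with `xbar` the column means and
#' `C` the sample covariance (`N - 1` denominator).  With
#' `cov_method = "pseudo"` a rank-truncated eigendecomposition replaces
#' `C^{-1}`, which handles feature matrices whose covariance is singular by
#' construction (constant features, or derivative blocks that are exact
#' linear functions of fit coefficients); the distance is then computed in
#' the column space of `C` and the effective dimension is the numerical rank.
#'
#' @param X Numeric `N x p` matrix.
#' @param cov_method `"solve"` (error on singular covariance) or `"pseudo"`
#'   (rank-truncated pseudo-inverse).
#' @param tol Relative eigenvalue tolerance for the rank decision.
#' @return Numeric vector of `N` squared distances with attribute `rank`, the
#'   effective feature dimension (equals `p` for `"solve"`).
#' @export
#' @examples
#' X <- matrix(rnorm(300), 100, 3)
#' d2 <- mahalanobis_d2(X)
#' sum(d2)  # equals rank * (N - 1) by the trace identity
mahalanobis_d2 <- function(X, cov_method = c("solve", "pseudo"), tol = 1e-10) {
  cov_method <- match.arg(cov_method)
  X <- as.matrix(X)
  N <- nrow(X)
  p <- ncol(X)
  if (N < 3L) abort("Need at least 3 rows to estimate a covariance.")
  ctr <- sweep(X, 2L, colMeans(X))
  C <- crossprod(ctr) / (N - 1)
  if (cov_method == "solve") {
    if (N <= p) {
      abort(paste0("N <= p: sample covariance is singular; prune features ",
                   "or use cov_method = \"pseudo\"."))
    }
    d2 <- tryCatch(
      stats::mahalanobis(X, colMeans(X), C),
      error = function(e) abort(paste0(
        "Singular covariance matrix; prune constant/collinear features or ",
        "use cov_method = \"pseudo\"."))
    )
    attr(d2, "rank") <- p
    return(d2)
  }
  # scale-equivariant pseudo-inverse: drop constant columns, work on the
  # correlation matrix so small-scale features are not truncated away
  m2 <- colMeans(ctr^2)
  varying <- !is_zero_var(m2, colMeans(X))
  if (!any(varying)) abort("All features are constant.")
  Z <- sweep(ctr[, varying, drop = FALSE], 2L,
             sqrt(m2[varying] * N / (N - 1)), "/")
  R <- crossprod(Z) / (N - 1)
  eig <- eigen(R, symmetric = TRUE)
  keep <- eig$values > tol * max(eig$values, 0) & eig$values > 0
  if (!any(keep)) abort("Covariance matrix has no positive eigenvalues.")
  W <- Z %*% eig$vectors[, keep, drop = FALSE]
  d2 <- drop(W^2 %*% (1 / eig$values[keep]))
  attr(d2, "rank") <- sum(keep)
  d2
}

# expected path length of an unsuccessful BST search among n points
path_length_norm <- function(n) {
  ifelse(n <= 1L, 0,
         ifelse(n == 2L, 1,
                2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n))
}

grow_itree <- function(X, idx, depth, limit) {
  n <- length(idx)
  if (n <= 1L || depth >= limit) return(list(size = n))
  # random feature among those varying in this node (up to a few attempts)
  feats <- sample.int(ncol(X), min(ncol(X), 8L))
  for (f in feats) {
    v <- X[idx, f]
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      split <- runif(1L, lo, hi)
      left <- idx[v < split]
      right <- idx[v >= split]
      return(list(
        feature = f, split = split,
        left = grow_itree(X, left, depth + 1L, limit),
        right = grow_itree(X, right, depth + 1L, limit)
      ))
    }
  }
  list(size = n)  # node constant in all sampled features
}

itree_depths <- function(node, X, rows, depth, acc) {
  if (is.null(node$feature)) {
    acc[rows] <- depth + path_length_norm(node$size)
    return(acc)
  }
  go_left <- X[rows, node$feature] < node$split
  if (any(go_left)) {
    acc <- itree_depths(node$left, X, rows[go_left], depth + 1L, acc)
  }
  if (any(!go_left)) {
    acc <- itree_depths(node$right, X, rows[!go_left], depth + 1L, acc)
  }
  acc
}

#' Isolation-forest anomaly scores
#'
#' Fits an ensemble of isolation trees, each grown on a random subsample by
#' recursively splitting on a random feature at a random value until points
#' are isolated or the depth limit `ceiling(log2(subsample))` is reached, and
#' scores every row by its average path length across trees.  The returned
#' decision value is `0.5 - 2^(-E[h(x)] / c(subsample))`, so anomalous rows
#' (short paths) receive the lowest scores.  Deterministic given `seed`.
#'
#' @param X Numeric `N x p` matrix, `N >= 2`.
#' @param n_trees Number of trees (default 100).
#' @param subsample Subsample size per tree (default 256, capped at `N`).
#' @param seed Mandatory integer seed.
#' @return Numeric vector of `N` decision values; lower = more anomalous.
#' @export
isolation_forest_scores <- function(X, n_trees = 100L, subsample = 256L,
                                    seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible scores.")
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 2L) abort("Need at least 2 rows.")
  psi <- min(as.integer(subsample), N)
  limit <- ceiling(log2(psi))
  withr::with_seed(seed, {
    depth_sum <- numeric(N)
    for (t in seq_len(n_trees)) {
      tree <- grow_itree(X, sample.int(N, psi), 0L, limit)
      depth_sum <- depth_sum +
        itree_depths(tree, X, seq_len(N), 0, numeric(N))
    }
  })
  0.5 - 2^(-(depth_sum / n_trees) / path_length_norm(psi))
}

#' Systematic mini-batch plan
#'
#' Partitions row indices `1..N` into `m` non-overlapping batches by
#' systematic sampling: batch `i` contains rows `i, i + m, i + 2m, ...`, so
#' row `r` belongs to batch `((r - 1) mod m) + 1`.  Adjacent (correlated)
#' rows land in different batches.
#'
#' @param N Number of rows (`N >= m`).
#' @param m Number of batches (default 18).
#' @return Integer vector of length `N` with batch assignments in `1..m`.
#' @export
plan_minibatches <- function(N, m = 18L) {
  N <- as.integer(N)
  m <- as.integer(m)
  if (N < m) abort(sprintf("N = %d < m = %d batches.", N, m))
  ((seq_len(N) - 1L) %% m) + 1L
}

#' One-class SVM anomaly scores with mini-batch training
#'
#' Trains one one-class SVM (RBF kernel) per mini-batch and scores each row
#' with the model trained on its own batch.  Defaults mirror common library
#' settings: `gamma = 1/p`, `nu = 0.5`, no feature rescaling.  Training is
#' deterministic, so repeated calls give identical scores.
#'
#' @param X Numeric `N x p` matrix.
#' @param batches Integer batch assignment from [plan_minibatches()], or
#'   `NULL` for a single batch.
#' @param gamma RBF kernel width (default `1/ncol(X)`).
#' @param nu One-class `nu` parameter (default 0.5).
#' @param min_batch Smallest batch size that can train a model (default 5).
#' @param score_all_batches If `TRUE`, score each row by the mean decision
#'   value across all batch models rather than its own batch's model.
#' @return Numeric vector of `N` decision values; lower = more anomalous.
#' @export
ocsvm_scores <- function(X, batches = NULL, gamma = NULL, nu = 0.5,
                         min_batch = 5L, score_all_batches = FALSE) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (is.null(batches)) batches <- rep(1L, N)
  stopifnot(length(batches) == N)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  sizes <- table(batches)
  if (any(sizes < min_batch)) {
    abort(sprintf("Batch of size %d < min_batch = %d; use fewer batches.",
                  min(sizes), min_batch))
  }
  models <- lapply(split(seq_len(N), batches), function(rows) {
    e1071::svm(X[rows, , drop = FALSE], type = "one-classification",
               kernel = "radial", gamma = gamma, nu = nu, scale = FALSE)
  })
  decision <- function(model, rows) {
    pr <- predict(model, X[rows, , drop = FALSE], decision.values = TRUE)
    drop(attr(pr, "decision.values"))
  }
  scores <- numeric(N)
  if (score_all_batches) {
    all_rows <- seq_len(N)
    mat <- vapply(models, decision, numeric(N), rows = all_rows)
    scores <- rowMeans(mat)
  } else {
    for (b in names(models)) {
      rows <- which(batches == as.integer(b))
      scores[rows] <- decision(models[[b]], rows)
    }
  }
  scores
}

#' Score feature stretches with an anomaly detector
#'
#' Applies one detector to the feature matrix of a feature tibble and returns
#' a per-stretch score table.  For `"mahalanobis"` the raw score is the
#' squared Mahalanobis distance (higher = more anomalous) and the effective
#' feature dimension is recorded for the downstream F-transform; for
#' `"iforest"` and `"ocsvm"` the raw score is the detector's decision value
#' (lower = more anomalous), later calibrated by [score_pvalues()].
#'
#' @param features A feature tibble from [moment_features()],
#'   [fda_features()] or [assemble_features()].
#' @param detector `"mahalanobis"`, `"iforest"` or `"ocsvm"`.
#' @param seed Integer seed (required for `"iforest"`).
#' @param cov_method Covariance handling for `"mahalanobis"`: `"auto"` uses a
#'   plain solve when the covariance is well-conditioned and falls back to
#'   the rank-truncated pseudo-inverse otherwise; `"solve"` and `"pseudo"`
#'   force one behaviour.
#' @param n_batches Mini-batches for `"ocsvm"` (default 18; reduced to a
#'   single batch when `N < n_batches`).
#' @param ... Further arguments passed to the detector
#'   ([isolation_forest_scores()], [ocsvm_scores()]).
#' @return A score tibble: anchor columns, `raw_score` and (for Mahalanobis)
#'   `d2`; attributes `detector`, `feature_set`, `dof` (effective feature
#'   dimension for Mahalanobis, 1 otherwise) and `seed`.
#' @export
#' @examples
#' g <- simulate_genotypes(n = 12, n_snps = 400, seed = 3)
#' s <- window_stats(g, window_size = 11)
#' f <- moment_features(s, stretch_size = 21)
#' head(score_anomalies(f, "mahalanobis", cov_method = "pseudo"))
score_anomalies <- function(features,
                            detector = c("mahalanobis", "iforest", "ocsvm"),
                            seed = NULL,
                            cov_method = c("auto", "solve", "pseudo"),
                            n_batches = 18L, ...) {
  detector <- match.arg(detector)
  cov_method <- match.arg(cov_method)
  X <- feature_matrix(features)
  res <- anchor_frame(features)
  dof <- 1L
  if (detector == "mahalanobis") {
    if (cov_method == "auto") {
      d2 <- tryCatch(mahalanobis_d2(X, "solve"), error = function(e) {
        inform("Covariance singular or ill-conditioned; using pseudo-inverse.")
        mahalanobis_d2(X, "pseudo")
      })
    } else {
      d2 <- mahalanobis_d2(X, cov_method)
    }
    dof <- attr(d2, "rank")
    res$raw_score <- as.numeric(d2)
    res$d2 <- as.numeric(d2)
  } else if (detector == "iforest") {
    if (is.null(seed)) abort("`seed` is required for the isolation forest.")
    res$raw_score <- isolation_forest_scores(X, seed = seed, ...)
  } else {
    batches <- if (nrow(X) >= n_batches) {
      plan_minibatches(nrow(X), n_batches)
    } else {
      rep(1L, nrow(X))
    }
    res$raw_score <- ocsvm_scores(X, batches = batches, ...)
  }
  attr(res, "detector") <- detector
  attr(res, "feature_set") <- attr(features, "feature_set")
  attr(res, "dof") <- dof
  attr(res, "seed") <- seed
  res
}
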