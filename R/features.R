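#' Cubic B-spline basis system on a stretch of windows
#'
#' Builds `n_basis` B-spline basis functions of the given order (4 = cubic) on
#' the domain `[1, stretch_size]` with equally spaced interior knots, and
#' evaluates the basis and its first and second analytic derivatives at the
#' integer points `1..stretch_size`.  Also precomputes the least-squares
#' projection used by [fit_basis_coef()] and the linear maps that carry fitted
#' coefficients to the re-fitted coefficients of the curve's first and second
#' derivatives.
#'
#' @param stretch_size Number of evaluation points `w` (must exceed `n_basis`).
#' @param n_basis Number of basis functions `B` (default 10).
#' @param order Spline order (default 4, i.e. cubic).
#' @return An object of class `spline_basis`: a list with `Phi`, `dPhi`,
#'   `ddPhi` (`w x B` evaluation matrices), `proj` (`B x w` least-squares
#'   projection), `deriv1`, `deriv2` (`B x w` maps returning derivative
#'   re-fit coefficients), `knots`, `n_basis`, `order`, `stretch_size`.
#' @export
#' @examples
#' b <- spline_basis(129)
#' range(rowSums(b$Phi))  # B-splines are a partition of unity
spline_basis <- function(stretch_size, n_basis = 10L, order = 4L) {
  stretch_size <- as.integer(stretch_size)
  n_basis <- as.integer(n_basis)
  order <- as.integer(order)
  if (n_basis < order) abort("`n_basis` must be >= the spline order.")
  if (stretch_size <= n_basis) abort("`stretch_size` must exceed `n_basis`.")
  breaks <- seq(1, stretch_size, length.out = n_basis - order + 2L)
  knots <- c(rep(1, order), breaks[-c(1L, length(breaks))],
             rep(stretch_size, order))
  t_eval <- seq_len(stretch_size)
  Phi <- splines::splineDesign(knots, t_eval, ord = order)
  dPhi <- splines::splineDesign(knots, t_eval, ord = order,
                                derivs = rep(1L, stretch_size))
  ddPhi <- splines::splineDesign(knots, t_eval, ord = order,
                                 derivs = rep(2L, stretch_size))
  gram <- crossprod(Phi)
  if (rcond(gram) < 1e-12) {
    abort("Basis evaluation matrix is rank-deficient; reduce `n_basis`.")
  }
  proj <- solve(gram, t(Phi))          # c = proj %*% y
  structure(list(
    Phi = Phi, dPhi = dPhi, ddPhi = ddPhi, proj = proj,
    deriv1 = (proj %*% dPhi) %*% proj,   # refit of f' values, as a map of y
    deriv2 = (proj %*% ddPhi) %*% proj,
    knots = knots, n_basis = n_basis, order = order,
    stretch_size = stretch_size
  ), class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> B = %d, order = %d on [1, %d] (%d interior knots)\n",
              x$n_basis, x$order, x$stretch_size, x$n_basis - x$order))
  invisible(x)
}

#' Least-squares B-spline coefficients of a sampled curve
#'
#' Ordinary least squares: `c = argmin ||y - Phi c||^2`.  No roughness
#' penalty, no randomness.
#'
#' @param y Numeric vector of length `stretch_size`.
#' @param basis A [spline_basis()].
#' @return Numeric vector of `n_basis` coefficients.
#' @export
fit_basis_coef <- function(y, basis) {
  stopifnot(inherits(basis, "spline_basis"))
  if (length(y) != basis$stretch_size || !all(is.finite(y))) {
    abort("`y` must be a finite vector of length `stretch_size`.")
  }
  drop(basis$proj %*% y)
}

#' Derivative ("velocity"/"acceleration") features of a fitted curve
#'
#' Evaluates the first or second derivative of the fitted spline at the
#' sample points via the analytic basis derivatives, then re-fits those
#' values on the same B-dimensional basis by least squares, yielding exactly
#' `n_basis` features per derivative order.
#'
#' @param coef Coefficients from [fit_basis_coef()].
#' @param basis A [spline_basis()].
#' @param deriv Derivative order, 1 or 2.
#' @return Numeric vector of `n_basis` re-fit coefficients.
#' @export
derivative_coef <- function(coef, basis, deriv = 1L) {
  stopifnot(inherits(basis, "spline_basis"))
  dmat <- switch(as.character(deriv), "1" = basis$dPhi, "2" = basis$ddPhi,
                 abort("`deriv` must be 1 or 2."))
  drop(basis$proj %*% (dmat %*% coef))
}

# Forward-order sliding-window matrix: row i = v[i:(i + w - 1)].
sliding_matrix <- function(v, w) {
  n_out <- length(v) - w + 1L
  cols <- vapply(seq_len(w), function(j) v[j:(j + n_out - 1L)],
                 numeric(n_out))
  matrix(cols, nrow = n_out, ncol = w)
}

stat_cols <- c("mu", "sigma2", "gamma", "beta", paste0("f", 1:4))

#' Stretches of consecutive windows
#'
#' Bookkeeping for the stretches of `stretch_size` consecutive windows
#' (stride one window) over a per-window statistics table.  Each stretch is
#' anchored at its centre window.
#'
#' @param stats A single-chromosome [window_stats()] tibble.
#' @param stretch_size Odd number of windows per stretch (`w`, default 129).
#' @return A tibble with `chrom`, `stretch` (index of the first window),
#'   `center_window` and `center_position`; empty with a warning when there
#'   are fewer than `stretch_size` windows.
#' @export
stretch_index <- function(stats, stretch_size = 129L) {
  stretch_size <- check_odd(stretch_size, "stretch_size")
  n_win <- nrow(stats)
  if (n_win < stretch_size) {
    warn(sprintf("Only %d windows < stretch_size = %d; no stretches.",
                 n_win, stretch_size))
    return(tibble(chrom = character(), stretch = integer(),
                  center_window = integer(), center_position = integer()))
  }
  k <- seq_len(n_win - stretch_size + 1L)
  ctr <- k + (stretch_size - 1L) %/% 2L
  tibble(chrom = stats$chrom[ctr], stretch = k,
         center_window = stats$window[ctr],
         center_position = stats$center_position[ctr])
}

feature_frame <- function(stats, stretch_size, feature_fun, feature_set,
                          extra_attrs = list()) {
  stopifnot(all(stat_cols %in% names(stats)))
  if (dplyr::n_distinct(stats$chrom) > 1L) {
    parts <- lapply(split(stats, factor(stats$chrom,
                                        levels = unique(stats$chrom))),
                    function(s) feature_frame(s, stretch_size, feature_fun,
                                              feature_set, extra_attrs))
    return(assemble_features(parts))
  }
  anchors <- stretch_index(stats, stretch_size)
  if (nrow(anchors) == 0L) return(anchors)
  blocks <- lapply(stat_cols, function(col) {
    feature_fun(sliding_matrix(stats[[col]], stretch_size), col)
  })
  res <- dplyr::bind_cols(anchors, as_tibble(do.call(cbind, blocks)))
  attr(res, "feature_set") <- feature_set
  attr(res, "stretch_size") <- stretch_size
  attr(res, "feature_cols") <- setdiff(names(res), names(anchors))
  for (nm in names(extra_attrs)) attr(res, nm) <- extra_attrs[[nm]]
  res
}

#' Moment features over stretches of windows
#'
#' For every stretch of `stretch_size` consecutive windows, computes the mean,
#' variance, skewness and excess kurtosis of each of the eight per-window
#' statistics across the stretch (same moment conventions as
#' [dist_moments()]), giving `4 * 8 = 32` features per stretch.  Feature
#' ordering is statistic-major, moment-minor.
#'
#' @param stats A [window_stats()] tibble (one or more chromosomes).
#' @param stretch_size Odd number of windows per stretch (`w`, default 129).
#' @return A feature tibble: anchor columns plus 32 feature columns named
#'   `<stat>_<moment>`; attributes `feature_set = "moments"`,
#'   `stretch_size`, `feature_cols`.
#' @export
moment_features <- function(stats, stretch_size = 129L) {
  feature_fun <- function(E, col) {
    m1 <- rowMeans(E)
    ctr <- E - m1
    m2 <- rowMeans(ctr^2)
    zero <- is_zero_var(m2, m1)
    skew <- ifelse(zero, 0, rowMeans(ctr^3) / m2^1.5)
    kurt <- ifelse(zero, 0, rowMeans(ctr^4) / m2^2 - 3)
    out <- cbind(m1, ifelse(zero, 0, m2), skew, kurt)
    colnames(out) <- paste0(col, "_", c("mean", "var", "skew", "kurt"))
    out
  }
  feature_frame(stats, stretch_size, feature_fun, "moments")
}

#' Functional-data-analysis features over stretches of windows
#'
#' Treats each per-window statistic as a curve over the `stretch_size`
#' windows of a stretch and represents it by `n_basis` cubic B-spline
#' coefficients (ordinary least squares), plus `n_basis` coefficients each
#' for the re-fitted first derivative ("velocity") and second derivative
#' ("acceleration") of the curve, capturing the autocorrelation that linkage
#' disequilibrium induces along the genome.  With defaults this yields
#' `3 * 10 * 8 = 240` features per stretch, ordered statistic-major with
#' blocks `[fit, d1, d2]`.
#'
#' @param stats A [window_stats()] tibble (one or more chromosomes).
#' @param stretch_size Odd number of windows per stretch (`w`, default 129).
#' @param n_basis Number of B-spline basis functions (`B`, default 10).
#' @param basis Optional precomputed [spline_basis()] (must match
#'   `stretch_size` and `n_basis`).
#' @return A feature tibble: anchor columns plus `3 * n_basis * 8` feature
#'   columns named `<stat>_{fit,d1,d2}<b>`; attributes
#'   `feature_set = "fda"`, `stretch_size`, `n_basis`, `feature_cols`.
#' @export
fda_features <- function(stats, stretch_size = 129L, n_basis = 10L,
                         basis = NULL) {
  stretch_size <- check_odd(stretch_size, "stretch_size")
  if (is.null(basis)) basis <- spline_basis(stretch_size, n_basis)
  stopifnot(inherits(basis, "spline_basis"),
            basis$stretch_size == stretch_size, basis$n_basis == n_basis)
  # all three blocks are linear in the sampled curve: one w x 3B map
  tmap <- t(rbind(basis$proj, basis$deriv1, basis$deriv2))
  b_lab <- sprintf("%02d", seq_len(n_basis))
  feature_fun <- function(E, col) {
    out <- E %*% tmap
    colnames(out) <- paste0(col, "_", rep(c("fit", "d1", "d2"), each = n_basis),
                            b_lab)
    out
  }
  feature_frame(stats, stretch_size, feature_fun, "fda",
                extra_attrs = list(n_basis = n_basis))
}

#' Combine per-chromosome feature tibbles
#'
#' Row-concatenates feature tibbles produced with the same feature set and
#' parameters, preserving `(chrom, anchor)` bookkeeping and attributes.
#'
#' @param parts A list of feature tibbles ([moment_features()] or
#'   [fda_features()] output).
#' @return A single feature tibble.
#' @export
assemble_features <- function(parts) {
  parts <- parts[vapply(parts, nrow, 0L) > 0L]
  if (length(parts) == 0L) abort("No non-empty feature tibbles to assemble.")
  sets <- unique(vapply(parts, function(p) attr(p, "feature_set"), ""))
  if (length(sets) != 1L) abort("Cannot mix feature sets (moments vs fda).")
  cols <- lapply(parts, names)
  if (length(unique(vapply(cols, paste, "", collapse = ","))) != 1L) {
    abort("Feature tibbles have inconsistent columns.")
  }
  res <- dplyr::bind_rows(parts)
  for (a in c("feature_set", "stretch_size", "n_basis", "feature_cols")) {
    attr(res, a) <- attr(parts[[1L]], a)
  }
  res
}

feature_matrix <- function(features) {
  cols <- attr(features, "feature_cols")
  if (is.null(cols)) {
    cols <- setdiff(names(features),
                    c("chrom", "stretch", "center_window", "center_position"))
  }
  as.matrix(features[cols])
}

anchor_frame <- function(features) {
  features[intersect(c("chrom", "stretch", "center_window", "center_position"),
                     names(features))]
}

#' Write a feature tibble to TSV (header line records the parameters)
#'
#' @param features A feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# feature_set=%s stretch_size=%s n_basis=%s",
    attr(features, "feature_set"), attr(features, "stretch_size"),
    attr(features, "n_basis") %||% "NA"), con)
  utils::write.table(features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
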