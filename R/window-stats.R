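#' Sliding SNP windows over a genotype matrix
#'
#' Enumerates all windows of `window_size` contiguous SNPs at a stride of one
#' SNP.  A window is addressed by the base-pair coordinate of its centre SNP,
#' so `window_size` must be odd.
#'
#' @param x A [geno_matrix()].
#' @param window_size Odd number of SNPs per window (`l`, default 51).
#' @return A tibble with one row per window: `chrom`, `window` (1-based index
#'   of the first SNP), `center_index` and `center_position`.  Empty, with a
#'   warning, when the chromosome has fewer than `window_size` SNPs.
#' @export
snp_windows <- function(x, window_size = 51L) {
  stopifnot(inherits(x, "geno_matrix"))
  window_size <- check_odd(window_size, "window_size")
  L <- ncol(x$G)
  if (L < window_size) {
    warn(sprintf("Chromosome %s has %d SNPs < window_size = %d; no windows.",
                 x$chrom, L, window_size))
    return(tibble(chrom = character(), window = integer(),
                  center_index = integer(), center_position = integer()))
  }
  k <- seq_len(L - window_size + 1L)
  center <- k + (window_size - 1L) %/% 2L
  tibble(chrom = x$chrom, window = k, center_index = center,
         center_position = x$positions[center])
}

#' Extract one SNP window as a genotype submatrix
#'
#' @param x A [geno_matrix()].
#' @param k 1-based index of the window's first SNP column.
#' @param window_size Number of SNPs in the window.
#' @return The `n x window_size` integer submatrix.
#' @export
snp_window <- function(x, k, window_size = 51L) {
  stopifnot(inherits(x, "geno_matrix"))
  if (k < 1L || k + window_size - 1L > ncol(x$G)) {
    abort("Window exceeds the SNP columns of `x`.")
  }
  x$G[, k:(k + window_size - 1L), drop = FALSE]
}

#' Scaled pairwise Manhattan distances between multilocus genotypes
#'
#' For every distinct pair of individuals `i < i'` in a window, computes the
#' Manhattan distance between their MLG strings divided by the number of SNPs:
#' `d(i, i') = (1/l) * sum_t |g_it - g_i't|`.  Distances therefore lie in
#' `[0, 2]`.
#'
#' @param M An `n x l` genotype matrix with `n >= 2`.
#' @return Numeric vector of `n (n - 1) / 2` distances in canonical
#'   upper-triangle order (`(1,2), (1,3), ..., (1,n), (2,3), ...`).
#' @export
pairwise_manhattan <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) abort("Need at least 2 individuals to form pairs.")
  as.vector(dist(M, method = "manhattan")) / ncol(M)
}

#' Moments of a distance (or any numeric) distribution
#'
#' Population (divide-by-count) central moments: mean, variance, skewness
#' `m3 / m2^1.5` and excess kurtosis `m4 / m2^2 - 3`.  Zero-variance input
#' returns skewness and kurtosis of 0 so downstream matrices stay finite.
#'
#' @param d Non-empty numeric vector.
#' @return Named numeric vector `c(mu, sigma2, gamma, beta)`.
#' @export
dist_moments <- function(d) {
  if (length(d) == 0L) abort("Empty distance vector.")
  m1 <- mean(d)
  ctr <- d - m1
  m2 <- mean(ctr^2)
  if (is_zero_var(m2, m1)) {
    return(c(mu = m1, sigma2 = 0, gamma = 0, beta = 0))
  }
  c(mu = m1, sigma2 = m2, gamma = mean(ctr^3) / m2^1.5,
    beta = mean(ctr^4) / m2^2 - 3)
}

# variance below the noise floor of a mean-m1 computation counts as zero
is_zero_var <- function(m2, m1) {
  m2 < .Machine$double.eps * (abs(m1) + 1)^2 * 100
}

#' Frequencies of the four most common multilocus genotypes
#'
#' An MLG is the exact string of an individual's \{0, 1, 2\} values across the
#' window; identical strings define the same MLG.  Frequencies are the sorted
#' multiset counts divided by `n`, padded with zeros when fewer than four
#' distinct MLGs occur.
#'
#' @param M An `n x l` genotype matrix.
#' @return Named numeric vector `c(f1, f2, f3, f4)` with
#'   `1 >= f1 >= f2 >= f3 >= f4 >= 0`.
#' @export
mlg_frequencies <- function(M) {
  M <- as.matrix(M)
  keys <- apply(M, 1L, paste, collapse = "")
  top4_freqs(keys)
}

top4_freqs <- function(keys) {
  counts <- sort(tabulate(match(keys, unique(keys))), decreasing = TRUE)
  f <- c(counts, 0L, 0L, 0L)[1:4] / length(keys)
  names(f) <- paste0("f", 1:4)
  f
}

#' Per-window summary statistics of MLG diversity
#'
#' Slides a window of `window_size` SNPs along the chromosome (stride one
#' SNP) and computes, for each window, eight statistics: the mean, variance,
#' skewness and kurtosis of the scaled pairwise Manhattan distances between
#' individuals' MLGs ([pairwise_manhattan()], [dist_moments()]) and the
#' frequencies of the four most common MLGs ([mlg_frequencies()]).
#'
#' @param x A [geno_matrix()].
#' @param window_size Odd number of SNPs per window (`l`, default 51).
#' @return A tibble with one row per window: `chrom`, `window`,
#'   `center_position`, `mu`, `sigma2`, `gamma`, `beta`, `f1`...`f4`; carries
#'   attribute `window_size`.
#' @export
#' @examples
#' g <- simulate_genotypes(n = 12, n_snps = 80, seed = 7)
#' s <- window_stats(g, window_size = 11)
#' head(s)
window_stats <- function(x, window_size = 51L) {
  stopifnot(inherits(x, "geno_matrix"))
  window_size <- check_odd(window_size, "window_size")
  wins <- snp_windows(x, window_size)
  if (nrow(wins) == 0L) return(wins)
  n <- nrow(x$G)
  # one digit string per individual: a window MLG is a substring
  row_str <- apply(x$G, 1L, paste, collapse = "")
  out <- matrix(NA_real_, nrow(wins), 8L)
  for (i in seq_len(nrow(wins))) {
    k <- wins$window[i]
    sub <- x$G[, k:(k + window_size - 1L), drop = FALSE]
    out[i, 1:4] <- dist_moments(pairwise_manhattan(sub))
    out[i, 5:8] <- top4_freqs(substr(row_str, k, k + window_size - 1L))
  }
  colnames(out) <- c("mu", "sigma2", "gamma", "beta", paste0("f", 1:4))
  res <- dplyr::bind_cols(wins[c("chrom", "window", "center_position")],
                          as_tibble(out))
  attr(res, "window_size") <- window_size
  res
}

#' Write per-window summary statistics to TSV
#'
#' @param stats Output of [window_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_odd <- function(x, name) {
  x <- as.integer(x)
  if (x < 1L || x %% 2L == 0L) {
    abort(sprintf("`%s` must be a positive odd integer (got %d).", name, x))
  }
  x
}
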