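#' Re-polarise a genotype matrix to minor-allele counts
#'
#' The scan pipeline counts alternate alleles as printed in the VCF; for
#' diversity images each column is re-polarised so the *minor* allele is
#' counted: columns whose mean exceeds 1 (alternate allele in the majority)
#' are flipped `g -> 2 - g`; columns with mean exactly 1 are left unflipped.
#' Polarisation is local to the supplied region.
#'
#' @param M Genotype matrix with entries in \{0, 1, 2\}.
#' @return Matrix of the same shape with every column mean at most 1.
#' @export
minor_allele_matrix <- function(M) {
  M <- as.matrix(M)
  flip <- colMeans(M) > 1
  M[, flip] <- 2L - M[, flip]
  M
}

#' Sort window rows by multilocus genotype magnitude
#'
#' Reorders the rows of a window matrix in ascending order of their L1 norm
#' (row sum of allele counts).  The sort is stable: rows with equal sums keep
#' their original relative order.
#'
#' @param M Genotype window matrix.
#' @return The row-sorted matrix.
#' @export
sort_window_rows <- function(M) {
  M <- as.matrix(M)
  M[order(rowSums(M)), , drop = FALSE]
}

#' MLG diversity image of an outlier region
#'
#' Builds the image matrix used to visualise local multilocus genotype
#' diversity at an anomalous data point.  The region spans the
#' `stretch_size + window_size - 1` SNPs that define the data point.  After
#' re-polarising to minor-allele counts, every `window_size`-SNP window
#' `k = 1..stretch_size` is extracted and its rows sorted by L1 norm
#' ([sort_window_rows()]); entry `(i, j)` of the image is then the mean of
#' the sorted matrices' entries for individual-rank `i` at SNP `j`, averaged
#' over all windows containing SNP `j`.  Values lie in `[0, 2]`: 0 =
#' homozygous major, 1 = heterozygous, 2 = homozygous minor.
#'
#' @param region An `n x (stretch_size + window_size - 1)` genotype matrix,
#'   or a [geno_matrix()] together with `at` (see [stretch_region()]).
#' @param window_size SNPs per window (`l`).
#' @param stretch_size Windows per stretch (`w`).
#' @param label Optional coordinate label (e.g. `"6:31324000 HLA-B"`).
#' @return A `diversity_image` object: the `n x (w + l - 1)` numeric matrix
#'   with attributes `window_size`, `stretch_size`, `label`.
#' @export
diversity_image <- function(region, window_size = 51L, stretch_size = 129L,
                            label = NULL) {
  M <- as.matrix(region)
  width <- stretch_size + window_size - 1L
  if (ncol(M) != width) {
    abort(sprintf("Region must have exactly w + l - 1 = %d SNP columns.", width))
  }
  M <- minor_allele_matrix(M)
  n <- nrow(M)
  num <- matrix(0, n, width)
  den <- numeric(width)
  for (k in seq_len(stretch_size)) {
    cols <- k:(k + window_size - 1L)
    num[, cols] <- num[, cols] + sort_window_rows(M[, cols, drop = FALSE])
    den[cols] <- den[cols] + 1
  }
  structure(sweep(num, 2L, den, "/"),
            window_size = window_size, stretch_size = stretch_size,
            label = label, class = c("diversity_image", "matrix"))
}

#' @export
print.diversity_image <- function(x, ...) {
  cat(sprintf("<diversity_image> %d individuals x %d SNPs%s\n", nrow(x),
              ncol(x),
              if (!is.null(attr(x, "label"))) paste0(" (", attr(x, "label"), ")")
              else ""))
  invisible(x)
}

#' Extract the genotype region underlying one stretch
#'
#' Stretch `k` of a chromosome covers windows `k .. k + w - 1`, i.e. the
#' `w + l - 1` SNP columns starting at SNP `k`.
#'
#' @param x A [geno_matrix()].
#' @param stretch 1-based index of the stretch's first window.
#' @param window_size SNPs per window (`l`).
#' @param stretch_size Windows per stretch (`w`).
#' @return The `n x (w + l - 1)` genotype submatrix.
#' @export
stretch_region <- function(x, stretch, window_size = 51L,
                           stretch_size = 129L) {
  stopifnot(inherits(x, "geno_matrix"))
  width <- stretch_size + window_size - 1L
  if (stretch < 1L || stretch + width - 1L > ncol(x$G)) {
    abort("Stretch region exceeds the SNP columns of `x`.")
  }
  x$G[, stretch:(stretch + width - 1L), drop = FALSE]
}

#' Manhattan-plot-ready records from a p-value table
#'
#' @param pvals A [score_pvalues()] tibble.
#' @param alpha Significance threshold recorded in the result (default the
#'   table's own, else `5e-8`).
#' @return A tibble with `chrom`, `center_position`, `neg_log10_p` and
#'   `significant`, in input order within chromosome; attribute `alpha`.
#' @export
manhattan_table <- function(pvals, alpha = NULL) {
  alpha <- alpha %||% attr(pvals, "alpha") %||% 5e-8
  out <- tibble(
    chrom = pvals$chrom,
    center_position = pvals$center_position,
    neg_log10_p = -log10(pvals$p_adjusted),
    significant = pvals$p_adjusted < alpha
  )
  attr(out, "alpha") <- alpha
  out
}

#' Write a diversity image matrix to TSV
#'
#' @param img A [diversity_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tsv <- function(img, path) {
  utils::write.table(unclass(img), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
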