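#' Simulate unphased diploid genotypes with local LD-like autocorrelation
#'
#' Generates `n` individuals at `L` biallelic SNPs as the sum of two
#' pseudo-haplotypes.  Per-site alternate-allele frequencies are drawn
#' uniformly from `freq_range`; each haplotype allele is Bernoulli with the
#' site frequency, except that with probability `ld_rho` it instead copies the
#' same haplotype's allele at the previous site.  This first-order copying
#' process induces the along-genome autocorrelation in diversity that linkage
#' disequilibrium produces in real data, without modelling recombination or
#' demography.
#'
#' @param n Number of individuals (>= 2).
#' @param n_snps Number of SNPs `L`.
#' @param freq_range Length-2 vector: alternate-allele frequencies are drawn
#'   uniformly from `[freq_range[1], freq_range[2]]`.
#' @param ld_rho Copying probability in `[0, 1)` controlling LD persistence.
#' @param spacing Mean base-pair spacing between adjacent SNPs (positions are
#'   cumulative sums of `Uniform(1, 2 * spacing - 1)` gaps).
#' @param chrom Chromosome label for the result.
#' @param seed Mandatory integer seed; the result is a deterministic function
#'   of the arguments.
#' @return A [geno_matrix()].
#' @export
#' @examples
#' g <- simulate_genotypes(n = 10, n_snps = 100, seed = 1)
#' dim(g)
simulate_genotypes <- function(n, n_snps, freq_range = c(0.05, 0.5),
                               ld_rho = 0.5, spacing = 500, chrom = "1",
                               seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible simulation.")
  stopifnot(n >= 2, n_snps >= 1, length(freq_range) == 2,
            freq_range[1] >= 0, freq_range[2] <= 1,
            freq_range[1] <= freq_range[2], ld_rho >= 0, ld_rho < 1)
  withr::with_seed(seed, {
    freqs <- runif(n_snps, freq_range[1], freq_range[2])
    hap <- function() {
      # n x L haplotype matrix with first-order copying
      H <- matrix(0L, n, n_snps)
      H[, 1L] <- rbinom(n, 1L, freqs[1L])
      if (n_snps > 1L) {
        copy <- matrix(runif(n * (n_snps - 1L)) < ld_rho, n)
        fresh <- matrix(rbinom(n * (n_snps - 1L), 1L, rep(freqs[-1L], each = n)), n)
        for (j in 2L:n_snps) {
          H[, j] <- ifelse(copy[, j - 1L], H[, j - 1L], fresh[, j - 1L])
        }
      }
      H
    }
    G <- hap() + hap()
    gaps <- ceiling(runif(n_snps, 1, 2 * spacing - 1))
    geno_matrix(G, cumsum(gaps), chrom = chrom)
  })
}

#' Inject an anomalous region into a genotype matrix
#'
#' Overwrites the genotypes in a contiguous SNP span with one of three
#' anomaly archetypes, leaving everything outside the span untouched:
#'
#' * `"excess_het"` — balancing-selection-like signal: genotypes in the span
#'   are resampled with heterozygote probability 0.9 (the remaining mass split
#'   evenly between the homozygotes).
#' * `"freq_collapse"` — collapse of MLG diversity: every individual carries
#'   one of two fixed multilocus genotype strings, at frequencies 0.5/0.5.
#' * `"dropout_artifact"` — technical-artifact-like signal: a random 30% of
#'   individuals are set homozygous reference across the span.
#'
#' @param x A [geno_matrix()].
#' @param span Integer range of SNP column indices (e.g. `2001:2400`).
#' @param kind One of `"excess_het"`, `"freq_collapse"`, `"dropout_artifact"`.
#' @param seed Integer seed for the anomaly's randomness.
#' @return A modified [geno_matrix()].
#' @export
inject_anomaly <- function(x, span, kind = c("excess_het", "freq_collapse",
                                             "dropout_artifact"), seed) {
  stopifnot(inherits(x, "geno_matrix"))
  if (missing(seed)) abort("`seed` is mandatory.")
  kind <- match.arg(kind)
  span <- as.integer(span)
  if (min(span) < 1L || max(span) > ncol(x$G)) {
    abort("`span` must lie within the SNP columns of `x`.")
  }
  n <- nrow(x$G)
  m <- length(span)
  withr::with_seed(seed, {
    block <- switch(kind,
      excess_het = matrix(
        sample(0:2, n * m, replace = TRUE, prob = c(0.05, 0.9, 0.05)), n, m),
      freq_collapse = {
        # two fixed MLG strings with background-like per-site frequencies:
        # a collapse of diversity, not an allele-frequency shift
        site_freq <- pmin(pmax(colMeans(x$G[, span, drop = FALSE]) / 2,
                               0.05), 0.95)
        mlg_a <- rbinom(m, 2L, site_freq)
        mlg_b <- rbinom(m, 2L, site_freq)
        carrier_a <- seq_len(n) <= ceiling(n / 2)  # deterministic 50/50 split
        t(vapply(carrier_a, function(a) if (a) mlg_a else mlg_b, integer(m)))
      },
      dropout_artifact = {
        block <- x$G[, span, drop = FALSE]
        hit <- sample(n, size = max(1L, round(0.3 * n)))
        block[hit, ] <- 0L
        block
      }
    )
    x$G[, span] <- block
  })
  x
}
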