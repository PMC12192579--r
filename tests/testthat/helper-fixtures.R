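# Shared fixtures, built in code at load time.

# tiny deterministic genotype matrix
tiny_geno <- function(n = 6, L = 20, seed = 42) {
  withr::with_seed(seed, {
    geno_matrix(matrix(sample(0:2, n * L, replace = TRUE), n, L),
                positions = sort(sample.int(L * 100, L)))
  })
}

# synthetic per-window statistics table (no genotypes needed): n_win windows
# of smooth-ish random curves in the 8 statistic columns
fake_stats <- function(n_win, seed = 7, chrom = "1") {
  withr::with_seed(seed, {
    smooth <- function() {
      x <- cumsum(rnorm(n_win, sd = 0.1))
      x - min(x) + 0.1
    }
    tibble::tibble(
      chrom = chrom, window = seq_len(n_win),
      center_position = 100L * seq_len(n_win),
      mu = smooth(), sigma2 = smooth(), gamma = rnorm(n_win),
      beta = rnorm(n_win), f1 = runif(n_win, 0.3, 0.6),
      f2 = runif(n_win, 0.1, 0.3), f3 = runif(n_win, 0.05, 0.1),
      f4 = runif(n_win, 0, 0.05)
    )
  })
}

# a minimal VCF text file; genotypes given as a character matrix
# (sites x samples) of GT strings
write_vcf_text <- function(path, chrom, pos, gt, ref = "A", alt = "G") {
  samples <- paste0("S", seq_len(ncol(gt)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  alt <- rep_len(alt, length(pos))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom, pos[i], ".", ref, alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}
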