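#' Genotype matrix for one chromosome
#'
#' A `geno_matrix` holds unphased diploid genotypes at biallelic SNPs for one
#' chromosome: an `n x L` integer matrix of alternate-allele counts in
#' \{0, 1, 2\} (one row per individual, one column per SNP), the base-pair
#' position of every SNP, and the sample identifiers.  Row order is the sample
#' order of the source VCF and is preserved by every downstream operation.
#'
#' @param G Integer matrix (`n x L`) with entries in \{0, 1, 2\}.
#' @param positions Strictly increasing integer vector of length `L`
#'   (1-based base-pair coordinates, as in VCF).
#' @param chrom Chromosome identifier (scalar character).
#' @param sample_ids Character vector of length `n`; defaults to
#'   `rownames(G)` or `"S1"..."Sn"`.
#'
#' @return An object of class `geno_matrix` with fields `chrom`, `positions`,
#'   `G` and `sample_ids`.
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 0L), 2), positions = c(100L, 200L),
#'                  chrom = "1")
#' g
geno_matrix <- function(G, positions, chrom = "1", sample_ids = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (nrow(G) < 2L) abort("`G` must have at least 2 individuals (rows).")
  if (ncol(G) < 1L) abort("`G` must have at least 1 SNP (column).")
  if (anyNA(G) || !all(G %in% 0:2)) {
    abort("All genotype entries must be alternate-allele counts in {0, 1, 2}.")
  }
  positions <- as.integer(positions)
  if (length(positions) != ncol(G)) {
    abort("`positions` must have one entry per SNP column.")
  }
  if (any(diff(positions) <= 0L)) {
    abort("`positions` must be strictly increasing.")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(G) %||% paste0("S", seq_len(nrow(G)))
  }
  if (length(sample_ids) != nrow(G)) {
    abort("`sample_ids` must have one entry per row of `G`.")
  }
  rownames(G) <- sample_ids
  colnames(G) <- NULL
  structure(
    list(chrom = as.character(chrom)[1], positions = positions, G = G,
         sample_ids = as.character(sample_ids)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> chrom %s: %d individuals x %d biallelic SNPs (%s-%s bp)\n",
    x$chrom, nrow(x$G), ncol(x$G), format(min(x$positions), big.mark = ","),
    format(max(x$positions), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$G)

#' Tidy view of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, SNP) combination and columns
#'   `chrom`, `sample`, `position`, `genotype`.
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(
    chrom = x$chrom,
    sample = rep(x$sample_ids, times = ncol(x$G)),
    position = rep(x$positions, each = nrow(x$G)),
    genotype = as.integer(x$G)
  )
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads one chromosome from a VCF 4.x file (plain or gzip-compressed),
#' keeping only sites with exactly one REF and one ALT allele.  The genotype of
#' each individual is encoded as its number of ALT alleles regardless of
#' phase; ALT is taken from the file as printed (no minor-allele
#' re-polarisation).  Sites with one or more missing or half-called genotypes
#' are dropped, with the number of dropped sites reported, so that every
#' downstream window is a complete \{0, 1, 2\} matrix.
#'
#' @param path Path to the VCF file.
#' @param chrom Chromosome to load.  `NULL` (default) is allowed only for
#'   single-chromosome files.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, chrom = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  chroms <- vcfR::getCHROM(vcf)
  if (is.null(chrom)) {
    uc <- unique(chroms)
    if (length(uc) != 1L) {
      abort("Multi-chromosome VCF: supply `chrom` explicitly.")
    }
    chrom <- uc
  }
  keep <- chroms == chrom & vcfR::is.biallelic(vcf)
  if (!any(keep)) {
    abort(sprintf("No biallelic sites found on chromosome '%s'.", chrom))
  }
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles; any site containing a missing allele call is dropped
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  alt_count[clean == "0/0"] <- 0L
  alt_count[clean == "0/1" | clean == "1/0"] <- 1L
  alt_count[clean == "1/1"] <- 2L
  complete <- !apply(is.na(alt_count), 1L, any)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d site(s) with missing genotype calls.", n_dropped))
  }
  if (!any(complete)) {
    abort(sprintf("No complete biallelic sites on chromosome '%s'.", chrom))
  }
  pos <- as.integer(vcfR::getPOS(vcf))[complete]
  G <- t(alt_count[complete, , drop = FALSE])
  ord <- order(pos)
  if (anyDuplicated(pos)) {
    dup <- duplicated(pos[ord])
    warn(sprintf("Dropped %d duplicate position(s).", sum(dup)))
    ord <- ord[!dup]
  }
  geno_matrix(G[, ord, drop = FALSE], pos[ord], chrom = chrom,
              sample_ids = colnames(gt))
}

#' Write a genotype matrix to a minimal VCF 4.2 file
#'
#' Emits one biallelic record per SNP with REF `A`, ALT `G` and unphased
#' genotypes `0/0`, `0/1`, `1/1` according to the alternate-allele count.  The
#' output round-trips through [read_vcf()].
#'
#' @param x A [geno_matrix()].
#' @param path Output file path (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", x$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t")
  )
  gt <- matrix(gt_codes[x$G + 1L], nrow = nrow(x$G))
  body <- paste(
    x$chrom, x$positions, ".", "A", "G", ".", "PASS", ".", "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Dump the encoded genotype matrix as TSV (debugging aid)
#'
#' @param x A [geno_matrix()].
#' @param path Output TSV path; rows are samples, columns are positions.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(x, path) {
  stopifnot(inherits(x, "geno_matrix"))
  df <- as.data.frame(x$G)
  names(df) <- paste0(x$chrom, ":", x$positions)
  df <- cbind(sample = x$sample_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
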