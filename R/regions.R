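#' Read a BED 4/5 file into a tibble
#'
#' BED coordinates are 0-based and half-open: an interval `[start, end)`
#' contains 0-based positions `start .. end - 1`.  That convention is kept
#' throughout the annotation functions; 1-based SNP positions are converted
#' internally when intersecting.
#'
#' @param path Path to a BED file (3-5 columns, tab-separated, optional
#'   `track`/`#` header lines).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED half-open 0-based
    end = GenomicRanges::end(gr)
  )
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (!is.null(meta$name)) out$name <- as.character(meta$name)
  if (!is.null(meta$score)) out$score <- as.numeric(meta$score)
  if (any(out$start >= out$end)) abort("BED intervals must have start < end.")
  out
}

#' Write intervals to BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundle annotation interval tracks
#'
#' Collects the interval tracks used to characterise outlier regions.  Genes
#' may contain several transcripts per `name`; only the longest transcript
#' (maximal `end - start`, ties resolved by file order) is retained, per the
#' usual convention for assigning positions to a single gene model.
#'
#' @param genes Tibble of gene/transcript intervals (`chrom`, `start`, `end`,
#'   `name`), BED half-open 0-based.
#' @param exons,utr5,utr3 Optional interval tibbles for genic sub-labels.
#'   Positions inside a gene but in none of these are labelled `intron`.
#' @param repeats Optional repeat-region intervals.
#' @param gc,crg Optional score tracks (`chrom`, `start`, `end`, `score`) for
#'   GC content and CRG alignability/mappability.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL,
                           repeats = NULL, gc = NULL, crg = NULL) {
  check_iv <- function(x, need_name = FALSE, need_score = FALSE) {
    if (is.null(x)) return(NULL)
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (need_name) stopifnot("name" %in% names(x))
    if (need_score) stopifnot("score" %in% names(x))
    if (any(x$start >= x$end)) abort("Intervals must have start < end.")
    x
  }
  genes <- check_iv(genes, need_name = TRUE)
  genes <- genes %>%
    mutate(.ord = dplyr::row_number(), .len = .data$end - .data$start) %>%
    group_by(.data$name) %>%
    dplyr::slice_max(.data$.len, n = 1L, with_ties = TRUE) %>%
    dplyr::slice_min(.data$.ord, n = 1L) %>%   # longest transcript, first on tie
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-".ord", -".len")
  structure(list(
    genes = genes, exons = check_iv(exons), utr5 = check_iv(utr5),
    utr3 = check_iv(utr3), repeats = check_iv(repeats),
    gc = check_iv(gc, need_score = TRUE), crg = check_iv(crg, need_score = TRUE)
  ), class = "annotation_set")
}

# For each 1-based position, the index of the first covering interval in the
# half-open 0-based track `iv` (row order = file order), or NA.
match_interval <- function(chrom, pos, iv) {
  if (is.null(iv) || nrow(iv) == 0L || length(pos) == 0L) {
    return(rep(NA_integer_, length(pos)))
  }
  # 1-based SNP position P sits in BED [start, end) iff start + 1 <= P <= end
  query <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  subject <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  suppressWarnings(
    GenomicRanges::findOverlaps(query, subject, select = "first"))
}

#' Label anchors with genomic annotation
#'
#' Classifies each anchor position as genic (inside the longest transcript of
#' any gene) or intergenic, and sub-labels genic anchors as `utr5`, `utr3`,
#' `exon` or `intron` with precedence UTR > exon > intron, so UTR records
#' nested inside exon records win.  Anchors on chromosomes absent from the
#' gene track are skipped with a warning.
#'
#' @param anchors Tibble with `chrom` and `center_position` (1-based), e.g.
#'   a [call_outliers()] result.
#' @param annotations An [annotation_set()].
#' @return `anchors` with added columns `region` (`"genic"`/`"intergenic"`),
#'   `subregion` (`NA` for intergenic) and `gene` (containing gene name or
#'   `NA`), plus `in_repeat` when a repeat track is available.
#' @export
intersect_annotations <- function(anchors, annotations) {
  stopifnot(inherits(annotations, "annotation_set"),
            all(c("chrom", "center_position") %in% names(anchors)))
  known <- unique(annotations$genes$chrom)
  unknown <- setdiff(unique(anchors$chrom), known)
  if (length(unknown) > 0L && nrow(annotations$genes) > 0L) {
    warn(paste0("Chromosome(s) absent from annotation: ",
                paste(unknown, collapse = ", "),
                "; their anchors are labelled intergenic."))
  }
  g_hit <- match_interval(anchors$chrom, anchors$center_position,
                          annotations$genes)
  genic <- !is.na(g_hit)
  sub <- rep(NA_character_, nrow(anchors))
  in_track <- function(track) {
    !is.na(match_interval(anchors$chrom, anchors$center_position, track))
  }
  sub[genic] <- "intron"
  if (!is.null(annotations$exons)) sub[genic & in_track(annotations$exons)] <- "exon"
  if (!is.null(annotations$utr5)) sub[genic & in_track(annotations$utr5)] <- "utr5"
  if (!is.null(annotations$utr3)) sub[genic & in_track(annotations$utr3)] <- "utr3"
  anchors$region <- ifelse(genic, "genic", "intergenic")
  anchors$subregion <- sub
  anchors$gene <- ifelse(genic, annotations$genes$name[g_hit], NA_character_)
  if (!is.null(annotations$repeats)) {
    anchors$in_repeat <- in_track(annotations$repeats)
  }
  anchors
}

#' Flag anchors in low-confidence (poorly alignable/mappable) regions
#'
#' An anchor is low-confidence when the CRG alignability/mappability score of
#' its covering track interval is at most 0.9 (the threshold is inclusive).
#' Anchors not covered by the track get `NA` with a warning.
#'
#' @param anchors Tibble with `chrom` and `center_position`.
#' @param crg_track Score track tibble (`chrom`, `start`, `end`, `score`),
#'   BED half-open 0-based.
#' @param threshold Inclusive low-confidence cutoff (default 0.9).
#' @return Logical vector, one entry per anchor.
#' @export
classify_low_confidence <- function(anchors, crg_track, threshold = 0.9) {
  hit <- match_interval(anchors$chrom, anchors$center_position, crg_track)
  if (anyNA(hit)) {
    warn(sprintf("%d anchor(s) not covered by the CRG track (NA returned).",
                 sum(is.na(hit))))
  }
  crg_track$score[hit] <= threshold
}

#' Multinomial goodness-of-fit test against expected proportions
#'
#' Tests whether category counts are consistent with the given expected
#' proportions.  For small totals an exact multinomial test is used: the
#' p-value is the total probability of all outcomes whose multinomial
#' probability does not exceed that of the observed outcome.  Beyond
#' `exact_max` (or when the outcome space is too large to enumerate) a
#' chi-squared goodness-of-fit approximation is used instead.  The returned
#' value carries attribute `method` recording which path was taken.
#'
#' @param observed Non-negative integer vector of category counts.
#' @param expected_props Probability vector summing to 1, same length.
#' @param exact_max Largest total count for the exact path (default 500).
#' @return The p-value, with attribute `method` (`"exact"` or `"chisq"`).
#' @export
#' @examples
#' multinomial_uniformity_test(c(5, 0), c(0.5, 0.5))  # exact: 0.0625
multinomial_uniformity_test <- function(observed, expected_props,
                                        exact_max = 500L) {
  stopifnot(length(observed) == length(expected_props), all(observed >= 0),
            all(expected_props >= 0))
  if (abs(sum(expected_props) - 1) > 1e-8) {
    abort("`expected_props` must sum to 1.")
  }
  n <- sum(observed)
  if (n == 0L) abort("Zero total count.")
  k <- length(observed)
  n_outcomes <- choose(n + k - 1, k - 1)
  if (n <= exact_max && n_outcomes <= 2e5) {
    obs_p <- stats::dmultinom(observed, prob = expected_props)
    total <- 0
    # enumerate all compositions of n into k parts
    rec <- function(prefix, remaining, idx) {
      if (idx == k) {
        pr <- stats::dmultinom(c(prefix, remaining), prob = expected_props)
        if (pr <= obs_p * (1 + 1e-7)) total <<- total + pr
        return(invisible())
      }
      for (v in 0:remaining) rec(c(prefix, v), remaining - v, idx + 1L)
    }
    rec(integer(0), n, 1L)
    p <- min(total, 1)
    attr(p, "method") <- "exact"
  } else {
    p <- suppressWarnings(
      stats::chisq.test(observed, p = expected_props)$p.value)
    attr(p, "method") <- "chisq"
  }
  p
}

#' Exact two-tailed binomial enrichment test
#'
#' Two-tailed exact binomial test by the minimum-likelihood method: the
#' p-value sums the probabilities of all outcomes whose binomial probability
#' does not exceed that of the observed count.
#'
#' @param x Observed number of outlier windows in the region of interest.
#' @param n Total number of outlier windows.
#' @param p Expected proportion of outlier windows in the region.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' binomial_enrichment_test(8, 10, 0.5)  # 0.109375
binomial_enrichment_test <- function(x, n, p) {
  stopifnot(x >= 0, x <= n, p >= 0, p <= 1)
  if (p == 0) return(if (x == 0) 1 else 0)
  if (p == 1) return(if (x == n) 1 else 0)
  stats::binom.test(x, n, p, alternative = "two.sided")$p.value
}

#' Permutation calibration of an enrichment test
#'
#' Linkage disequilibrium correlates adjacent windows, so the nominal
#' p-values of count-based tests can be anti-conservative.  This routine
#' recomputes the test on `n_perm` random permutations of the label vector
#' and returns the fraction of permuted p-values strictly smaller than the
#' observed one.
#'
#' @param labels Vector of per-window labels (e.g. chromosome or region).
#' @param test_fn Function taking a label vector and returning a p-value.
#' @param n_perm Number of permutations (default `1e4`).
#' @param seed Mandatory integer seed.
#' @return The permutation p-value (a fraction in `[0, 1]`), with attribute
#'   `observed` holding the observed test p-value.
#' @export
permutation_pvalue <- function(labels, test_fn, n_perm = 1e4L, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  observed <- as.numeric(test_fn(labels))
  frac <- withr::with_seed(seed, {
    smaller <- 0L
    for (i in seq_len(n_perm)) {
      if (as.numeric(test_fn(sample(labels))) < observed) {
        smaller <- smaller + 1L
      }
    }
    smaller / n_perm
  })
  attr(frac, "observed") <- observed
  frac
}

#' Rank genes by their most significant overlapping outlier window
#'
#' Each gene (longest transcript) is scored by the minimum adjusted p-value
#' across the outlier windows whose anchor falls inside it; genes with no
#' overlapping outlier window are absent.  Genes are sorted by ascending
#' score, ties broken by genomic order.  The ranked symbol list is suitable
#' input for downstream GO-enrichment tools.
#'
#' @param outliers A [call_outliers()] tibble (needs `chrom`,
#'   `center_position`, `p_adjusted`).
#' @param annotations An [annotation_set()] (or a bare gene interval tibble).
#' @return A tibble with `rank`, `gene`, `p_min`, `n_windows`, `chrom`,
#'   `start`, `end`.
#' @export
rank_genes <- function(outliers, annotations) {
  genes <- if (inherits(annotations, "annotation_set")) {
    annotations$genes
  } else {
    annotations
  }
  hit <- match_interval(outliers$chrom, outliers$center_position, genes)
  tab <- tibble(gene_row = hit, p = outliers$p_adjusted) %>%
    filter(!is.na(.data$gene_row)) %>%
    group_by(.data$gene_row) %>%
    summarise(p_min = min(.data$p), n_windows = dplyr::n(), .groups = "drop")
  res <- tibble(
    gene = genes$name[tab$gene_row], p_min = tab$p_min,
    n_windows = tab$n_windows, chrom = genes$chrom[tab$gene_row],
    start = genes$start[tab$gene_row], end = genes$end[tab$gene_row]
  ) %>%
    arrange(.data$p_min, .data$chrom, .data$start)
  res$rank <- seq_len(nrow(res))
  select(res, "rank", dplyr::everything())
}

#' Write a ranked gene list (one symbol per line)
#'
#' @param ranked A [rank_genes()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ranked, path) {
  writeLines(ranked$gene, path)
  invisible(path)
}
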