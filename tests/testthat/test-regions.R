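genes_fx <- tibble::tibble(
  chrom = c("1", "1", "2"),
  start = c(100L, 100L, 50L),
  end   = c(500L, 900L, 200L),
  name  = c("GENE_A", "GENE_A", "GENE_B")   # two transcripts for GENE_A
)
exons_fx <- tibble::tibble(chrom = c("1", "1"), start = c(100L, 700L),
                           end = c(200L, 900L))
utr5_fx <- tibble::tibble(chrom = "1", start = 100L, end = 150L)

test_that("the longest transcript is retained per gene", {
  ann <- annotation_set(genes_fx)
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(ann$genes$end[ann$genes$name == "GENE_A"], 900L)
})

test_that("anchors get genic/intergenic labels with half-open BED semantics", {
  ann <- annotation_set(genes_fx, exons = exons_fx, utr5 = utr5_fx)
  anchors <- tibble::tibble(
    chrom = c("1", "1", "1", "1", "1", "2"),
    # 1-based positions: BED [100, 900) covers 1-based 101..900
    center_position = c(101L, 900L, 901L, 180L, 650L, 60L)
  )
  lab <- intersect_annotations(anchors, ann)
  expect_equal(lab$region,
               c("genic", "genic", "intergenic", "genic", "genic", "genic"))
  # interval end is outside the half-open interval
  expect_equal(lab$region[3], "intergenic")
  # precedence: UTR > exon > intron
  expect_equal(lab$subregion[1], "utr5")     # 101 in utr5 [100,150)
  expect_equal(lab$subregion[4], "exon")     # 180 in exon, past the UTR
  expect_equal(lab$subregion[5], "intron")   # 650 in gene, no exon
  expect_true(is.na(lab$subregion[3]))
  expect_equal(lab$gene[1], "GENE_A")
})

test_that("every anchor gets exactly one region label even without annotation", {
  empty <- annotation_set(tibble::tibble(chrom = character(),
                                         start = integer(), end = integer(),
                                         name = character()))
  anchors <- tibble::tibble(chrom = "1", center_position = c(10L, 20L))
  lab <- intersect_annotations(anchors, empty)
  expect_equal(lab$region, c("intergenic", "intergenic"))
  ann <- annotation_set(genes_fx)
  lab2 <- suppressWarnings(intersect_annotations(
    tibble::tibble(chrom = "chrX", center_position = 5L), ann))
  expect_equal(lab2$region, "intergenic")
})

test_that("CRG low-confidence classification is inclusive at 0.9", {
  crg <- tibble::tibble(chrom = "1", start = c(0L, 100L, 200L),
                        end = c(100L, 200L, 300L),
                        score = c(0.9, 1.0, 0.89))
  anchors <- tibble::tibble(chrom = "1", center_position = c(50L, 150L, 250L))
  expect_equal(classify_low_confidence(anchors, crg), c(TRUE, FALSE, TRUE))
  expect_warning(
    lc <- classify_low_confidence(
      tibble::tibble(chrom = "1", center_position = 999L), crg),
    "not covered")
  expect_true(is.na(lc))
})

test_that("BED files round-trip through the reader and writer", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(genes_fx, path)
  back <- read_bed(path)
  expect_equal(back$chrom, genes_fx$chrom)
  expect_equal(back$start, genes_fx$start)
  expect_equal(back$end, genes_fx$end)
  expect_equal(back$name, genes_fx$name)
})

test_that("the exact multinomial test enumerates minimum-likelihood outcomes", {
  p <- multinomial_uniformity_test(c(5L, 0L), c(0.5, 0.5))
  expect_equal(as.numeric(p), 0.0625)       # 2 * 0.5^5
  expect_equal(attr(p, "method"), "exact")
  # relabelling categories together with their expectations changes nothing
  p2 <- multinomial_uniformity_test(c(0L, 5L), c(0.5, 0.5))
  expect_equal(as.numeric(p2), as.numeric(p))
  p3 <- multinomial_uniformity_test(c(3L, 1L, 6L), c(0.3, 0.1, 0.6))
  p4 <- multinomial_uniformity_test(c(6L, 3L, 1L), c(0.6, 0.3, 0.1))
  expect_equal(as.numeric(p3), as.numeric(p4))
  # the chi-squared path returns 1 for perfectly proportional counts
  pc <- multinomial_uniformity_test(c(300L, 300L), c(0.5, 0.5),
                                    exact_max = 10L)
  expect_equal(attr(pc, "method"), "chisq")
  expect_equal(as.numeric(pc), 1)
  expect_error(multinomial_uniformity_test(c(0L, 0L), c(0.5, 0.5)), "Zero")
  expect_error(multinomial_uniformity_test(c(1L, 1L), c(0.5, 0.4)), "sum")
})

test_that("the two-tailed binomial test uses the minimum-likelihood rule", {
  expect_equal(binomial_enrichment_test(8L, 10L, 0.5), 0.109375)
  expect_equal(binomial_enrichment_test(10L, 10L, 1), 1)
  expect_equal(binomial_enrichment_test(5L, 10L, 0.5), 1)  # at the mode
  # reduces to doubling the smaller tail at p = 0.5 (away from the centre)
  for (n in 2:12) {
    for (x in setdiff(0:n, if (n %% 2 == 0) n / 2 else integer(0))) {
      lo <- min(x, n - x)
      expected <- min(1, 2 * pbinom(lo, n, 0.5))
      expect_equal(binomial_enrichment_test(x, n, 0.5), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("permutation p-values are seeded, degenerate-safe and detect enrichment", {
  # constant labels: every permutation identical, nothing strictly smaller
  tf <- function(lab) binomial_enrichment_test(sum(lab == "a"), length(lab), 0.5)
  expect_equal(as.numeric(permutation_pvalue(rep("a", 10), tf, 100L, seed = 1)), 0)
  # observed p of 1: no permutation can beat it strictly
  tf1 <- function(lab) 1
  expect_equal(as.numeric(permutation_pvalue(c("a", "b", "a"), tf1, 50L, seed = 1)), 0)
  # reproducibility under the same seed
  labs <- rep(c("a", "b"), c(30, 20))
  tf2 <- function(lab) binomial_enrichment_test(sum(lab[1:25] == "a"), 25L, 0.6)
  r1 <- permutation_pvalue(labs, tf2, 200L, seed = 9)
  r2 <- permutation_pvalue(labs, tf2, 200L, seed = 9)
  expect_identical(r1, r2)
})

test_that("planted extreme enrichment survives permutation calibration", {
  # 60 windows, 50 in category "x" of expected share 0.2: extreme enrichment
  labs <- rep(c("x", "y"), c(50, 10))
  tf <- function(lab) binomial_enrichment_test(sum(lab == "x"), length(lab), 0.2)
  frac <- permutation_pvalue(labs, tf, n_perm = 1e4L, seed = 11)
  expect_lte(as.numeric(frac), 0.001)
})

test_that("gene ranking equals a brute-force per-gene minimum scan", {
  withr::with_seed(20, {
    genes <- tibble::tibble(
      chrom = "1", start = seq(0L, 8000L, by = 2000L),
      end = seq(1000L, 9000L, by = 2000L),
      name = paste0("G", 1:5))
    outliers <- tibble::tibble(
      chrom = "1",
      center_position = sample.int(9500L, 20),
      p_adjusted = 10^-runif(20, 8, 20))
  })
  ranked <- rank_genes(outliers, annotation_set(genes))
  # brute force over genes x windows
  for (i in seq_len(nrow(genes))) {
    inside <- outliers$center_position > genes$start[i] &
      outliers$center_position <= genes$end[i]
    if (!any(inside)) {
      expect_false(genes$name[i] %in% ranked$gene)
    } else {
      expect_equal(ranked$p_min[ranked$gene == genes$name[i]],
                   min(outliers$p_adjusted[inside]))
    }
  }
  expect_true(!is.unsorted(ranked$p_min))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  # explicit ordering: smaller minimum ranks first
  o2 <- tibble::tibble(chrom = "1", center_position = c(500L, 2500L),
                       p_adjusted = c(1e-9, 1e-12))
  r2 <- rank_genes(o2, annotation_set(genes))
  expect_equal(r2$gene, c("G2", "G1"))
})
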