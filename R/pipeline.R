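#' Configuration for a genome anomaly scan
#'
#' Bundles and validates every tunable parameter of the scan.  Defaults
#' reproduce the standard analysis settings: 51-SNP windows, 129-window
#' stretches, 10 cubic B-spline basis functions, all six method combinations,
#' a genome-wide Bonferroni threshold of `5e-8` and 18 SVM mini-batches.
#'
#' @param window_size Odd number of SNPs per window (`l`).
#' @param stretch_size Odd number of windows per stretch (`w`).
#' @param n_basis B-spline basis functions for FDA features (`B`).
#' @param methods Character vector of method names, a subset of
#'   `"MD-M"`, `"MD-F"`, `"IF-M"`, `"IF-F"`, `"SVM-M"`, `"SVM-F"`
#'   (detector `MD`/`IF`/`SVM` crossed with feature set `M`oments/`F`DA).
#' @param alpha Outlier-calling threshold on adjusted p-values.
#' @param seed Master seed; all stochastic stages derive their seeds from it.
#' @param n_batches Mini-batches for SVM training.
#' @param n_perm Permutations for enrichment calibration.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_size = 51L, stretch_size = 129L, n_basis = 10L,
                        methods = c("MD-M", "MD-F", "IF-M", "IF-F",
                                    "SVM-M", "SVM-F"),
                        alpha = 5e-8, seed = 1L, n_batches = 18L,
                        n_perm = 1e4L) {
  window_size <- check_odd(window_size, "window_size")
  stretch_size <- check_odd(stretch_size, "stretch_size")
  all_methods <- c("MD-M", "MD-F", "IF-M", "IF-F", "SVM-M", "SVM-F")
  methods <- as.character(methods)
  if (length(methods) == 0L || !all(methods %in% all_methods)) {
    abort(paste0("`methods` must be a non-empty subset of: ",
                 paste(all_methods, collapse = ", ")))
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(list(
    window_size = window_size, stretch_size = stretch_size,
    n_basis = as.integer(n_basis), methods = methods, alpha = alpha,
    seed = as.integer(seed), n_batches = as.integer(n_batches),
    n_perm = as.integer(n_perm)
  ), class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config>\n")
  cat(sprintf("  window_size = %d, stretch_size = %d, n_basis = %d\n",
              x$window_size, x$stretch_size, x$n_basis))
  cat(sprintf("  methods = %s\n", paste(x$methods, collapse = ", ")))
  cat(sprintf("  alpha = %g, seed = %d, n_batches = %d, n_perm = %d\n",
              x$alpha, x$seed, x$n_batches, x$n_perm))
  invisible(x)
}

#' Read a scan configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [scan_config()]; missing keys take the defaults.
#' @return A `scan_config`.
#' @export
read_scan_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("The 'yaml' package is required to read config files.")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(scan_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort(paste0("Unknown config key(s): ",
                                paste(bad, collapse = ", ")))
  do.call(scan_config, vals)
}

method_detector <- function(method) {
  c(MD = "mahalanobis", IF = "iforest",
    SVM = "ocsvm")[[sub("-.*$", "", method)]]
}

method_feature_set <- function(method) {
  c(M = "moments", F = "fda")[[sub("^.*-", "", method)]]
}

#' Run the full anomaly scan
#'
#' Executes the whole workflow on one or more chromosomes: per-window
#' summary statistics ([window_stats()]), moment and/or FDA features
#' ([moment_features()], [fda_features()]) assembled across chromosomes,
#' anomaly scores for every requested method ([score_anomalies()]),
#' inflation-corrected p-values ([score_pvalues()]) and Bonferroni outlier
#' calls ([call_outliers()]).  The run is a pure function of
#' `(genotypes, config)`; each stochastic method derives its seed from the
#' master seed.
#'
#' @param genotypes A [geno_matrix()], a list of them (one per chromosome),
#'   or a character vector of VCF paths.
#' @param config A [scan_config()].
#' @param out_dir Optional directory; when given, every stage writes its TSV
#'   artifact there.
#' @return An object of class `mlg_scan`: a list with `stats` (per-window
#'   statistics), `features` (per feature set), `pvalues` and `calls` (per
#'   method) and `config`.  Use [tidy()], [glance()] and
#'   [ggplot2::autoplot()] on it.
#' @export
#' @examples
#' g <- simulate_genotypes(n = 20, n_snps = 800, seed = 5)
#' cfg <- scan_config(window_size = 11, stretch_size = 31,
#'                    methods = c("MD-M", "IF-M"), seed = 5)
#' scan <- mlg_scan(g, cfg)
#' glance(scan)
mlg_scan <- function(genotypes, config = scan_config(), out_dir = NULL) {
  stopifnot(inherits(config, "scan_config"))
  if (inherits(genotypes, "geno_matrix")) genotypes <- list(genotypes)
  if (is.character(genotypes)) genotypes <- lapply(genotypes, read_vcf)
  if (!all(vapply(genotypes, inherits, TRUE, "geno_matrix"))) {
    abort("`genotypes` must be geno_matrix objects or VCF paths.")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, writer, name) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }

  stats <- dplyr::bind_rows(
    lapply(genotypes, window_stats, window_size = config$window_size))
  emit(stats, write_stats_tsv, "window_stats.tsv")

  sets <- unique(vapply(config$methods, method_feature_set, ""))
  features <- list()
  if ("moments" %in% sets) {
    features$moments <- emit(
      moment_features(stats, config$stretch_size),
      write_features_tsv, "features_moments.tsv")
  }
  if ("fda" %in% sets) {
    features$fda <- emit(
      fda_features(stats, config$stretch_size, config$n_basis),
      write_features_tsv, "features_fda.tsv")
  }

  pvalues <- list()
  calls <- list()
  for (i in seq_along(config$methods)) {
    method <- config$methods[i]
    feats <- features[[method_feature_set(method)]]
    scores <- score_anomalies(
      feats, detector = method_detector(method),
      seed = config$seed + i, n_batches = config$n_batches)
    pv <- score_pvalues(scores)
    pvalues[[method]] <- pv
    calls[[method]] <- call_outliers(pv, config$alpha)
    if (!is.null(out_dir)) {
      utils::write.table(pv, file.path(out_dir,
                                       sprintf("pvalues_%s.tsv", method)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(calls[[method]],
                         file.path(out_dir, sprintf("calls_%s.tsv", method)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  structure(list(stats = stats, features = features, pvalues = pvalues,
                 calls = calls, config = config),
            class = "mlg_scan")
}

#' @export
print.mlg_scan <- function(x, ...) {
  cat(sprintf("<mlg_scan> %d chromosome(s), %d window(s), %d stretch(es)\n",
              dplyr::n_distinct(x$stats$chrom), nrow(x$stats),
              nrow(x$features[[1]])))
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-stretch results of a scan, one row per (method, stretch)
#'
#' @param x An [mlg_scan()] object.
#' @param ... Unused.
#' @return A tibble with `method`, anchor columns, `raw_score`, `d2`,
#'   `p_raw`, `p_adjusted` and `significant`.
#' @export
tidy.mlg_scan <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$pvalues), function(m) {
    pv <- x$pvalues[[m]]
    pv$method <- m
    pv$significant <- pv$p_adjusted < x$config$alpha
    select(pv, "method", dplyr::everything())
  }))
}

#' One-row-per-method summary of a scan
#'
#' @param x An [mlg_scan()] object.
#' @param ... Unused.
#' @return A tibble with `method`, `n` (stretches tested), `dof` (effective
#'   feature dimension used in the F transform), `lambda` (inflation
#'   factor), `n_outliers` and `n_peaks`.
#' @export
glance.mlg_scan <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$pvalues), function(m) {
    tibble(method = m, n = nrow(x$pvalues[[m]]),
           dof = attr(x$pvalues[[m]], "dof"),
           lambda = attr(x$pvalues[[m]], "lambda"),
           n_outliers = nrow(x$calls[[m]]),
           n_peaks = attr(x$calls[[m]], "n_peaks"))
  }))
}
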