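#' Shift-log transform of raw anomaly scores
#'
#' Detector decision values can be negative and heavily skewed; before
#' calibration they are log-transformed to increase the spread of the
#' distribution, with a positivity shift:
#' `s' = log(s - min(s) + eps)` where `eps = 1e-6 * range(s)`.  The transform
#' is strictly increasing in `s`.
#'
#' @param s Finite numeric vector of scores.
#' @return Transformed scores of the same length.
#' @export
transform_scores <- function(s) {
  if (!all(is.finite(s))) abort("Scores must be finite.")
  rng <- max(s) - min(s)
  if (rng == 0) abort("Constant score vector: nothing to transform.")
  log(s - min(s) + 1e-6 * rng)
}

#' F-distribution p-values for squared Mahalanobis distances
#'
#' Squared Mahalanobis distances from a sample mean and covariance follow a
#' Hotelling T-squared law, which maps to an F distribution:
#' `F = D2 * (N - p) / (p * (N - 1)) ~ F(p, N - p)`.  The p-value is the
#' upper-tail probability at that statistic.  Values that underflow to zero
#' are floored at `.Machine$double.xmin` so downstream quantile work stays
#' finite.
#'
#' @param d2 Vector of squared distances.
#' @param N Number of observations used to estimate mean and covariance.
#' @param p Feature dimension (effective rank).
#' @return Vector of upper-tail p-values in `(0, 1]`.
#' @export
d2_to_pvalues <- function(d2, N, p) {
  if (N <= p || p < 1L) abort("Require N > p >= 1 for the F transform.")
  f_stat <- d2 * (N - p) / (p * (N - 1))
  pmax(pf(f_stat, p, N - p, lower.tail = FALSE), .Machine$double.xmin)
}

#' Genomic-control inflation factor from a p-value distribution
#'
#' Converts p-values to observed chi-squared (1 d.f.) quantiles via the
#' upper-tail quantile function, pairs the sorted values with expected
#' chi-squared(1) quantiles at uniform plotting positions `(i - 0.5) / N`,
#' and fits a linear regression through the origin; the slope is the
#' inflation factor `lambda`.  Well-calibrated p-values give `lambda = 1`.
#'
#' `lambda` is meant to measure *background* inflation, but the regression
#' is dominated by its largest quantiles, exactly where genuine anomalies
#' accumulate; a strong true signal would otherwise masquerade as inflation
#' and deflate itself away.  The fit therefore uses only the smallest
#' `1 - trim` fraction of the paired order statistics (default: the upper
#' decile is excluded).  Under a purely scaled null the slope is unaffected
#' by trimming.
#'
#' @param p_raw Vector of p-values in `(0, 1]` (length >= 10).  Values equal
#'   to 1 are clamped to `1 - 1/(2N)` before the quantile transform.
#' @param trim Fraction of the most extreme quantile pairs excluded from the
#'   regression (default 0.1; 0 reproduces the all-quantile fit).
#' @return The scalar inflation factor `lambda`.
#' @export
#' @examples
#' estimate_lambda((seq_len(1000) - 0.5) / 1000)  # exactly 1
estimate_lambda <- function(p_raw, trim = 0.1) {
  N <- length(p_raw)
  if (N < 10L) abort("Need at least 10 p-values to estimate lambda.")
  if (any(p_raw <= 0)) abort("p-values of 0 cannot be mapped to quantiles.")
  if (any(p_raw > 1)) abort("p-values must lie in (0, 1].")
  if (trim < 0 || trim >= 1) abort("`trim` must lie in [0, 1).")
  p <- pmin(p_raw, 1 - 1 / (2 * N))
  q_obs <- sort(qchisq(p, df = 1, lower.tail = FALSE))
  q_exp <- sort(qchisq((seq_len(N) - 0.5) / N, df = 1, lower.tail = FALSE))
  keep <- seq_len(N - floor(trim * N))
  sum(q_exp[keep] * q_obs[keep]) / sum(q_exp[keep]^2)  # through the origin
}

#' Deflate p-values by an inflation factor
#'
#' Divides the observed chi-squared(1 d.f.) quantiles by `lambda` and
#' converts back to upper-tail p-values.  `lambda = 1` returns the input
#' unchanged; `lambda > 1` makes every p-value larger (less significant).
#'
#' @param p_raw Vector of p-values in `(0, 1]`.
#' @param lambda Positive inflation factor, typically from
#'   [estimate_lambda()].
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p_raw, lambda) {
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (lambda == 1) return(p_raw)
  q <- qchisq(p_raw, df = 1, lower.tail = FALSE)
  pmax(pchisq(q / lambda, df = 1, lower.tail = FALSE), .Machine$double.xmin)
}

#' Calibrated p-values for a score table
#'
#' Turns raw anomaly scores into inflation-corrected p-values.  Mahalanobis
#' scores are referred directly to the F distribution with their effective
#' feature dimension ([d2_to_pvalues()]).  Isolation-forest and one-class-SVM
#' decision values are first shift-log transformed ([transform_scores()]),
#' then treated as one-dimensional Mahalanobis distances (squared
#' standardised score referred to `F(1, N - 1)`).
#'
#' The inflation factor is estimated in two passes so that genuine anomalies
#' do not masquerade as background inflation: a robust trimmed fit
#' ([estimate_lambda()]) yields provisional outlier calls at `alpha`, and the
#' final `lambda` is the full quantile regression on the remaining
#' (background) p-values.  Following genomic-control convention the
#' correction is only applied when it deflates significance
#' (`lambda` is clamped at 1 when adjusting).
#'
#' @param scores A score tibble from [score_anomalies()].
#' @param alpha Threshold used only to exclude provisional outliers from the
#'   background set of the `lambda` refinement (default `5e-8`).
#' @return The tibble with added columns `d2`, `p_raw`, `p_adjusted`;
#'   attributes `lambda` (final background estimate), `dof`, `detector`,
#'   `feature_set`.
#' @export
score_pvalues <- function(scores, alpha = 5e-8) {
  detector <- attr(scores, "detector")
  if (is.null(detector)) abort("`scores` must come from score_anomalies().")
  N <- nrow(scores)
  if (detector == "mahalanobis") {
    dof <- attr(scores, "dof")
    d2 <- scores$d2
  } else {
    dof <- 1L
    s <- transform_scores(scores$raw_score)
    d2 <- (s - mean(s))^2 / stats::var(s)
    scores$d2 <- d2
  }
  scores$p_raw <- d2_to_pvalues(d2, N, dof)
  lambda_robust <- estimate_lambda(scores$p_raw, trim = 0.1)
  background <- adjust_pvalues(scores$p_raw, max(1, lambda_robust)) >= alpha
  lambda <- if (sum(background) >= 10L) {
    estimate_lambda(scores$p_raw[background], trim = 0)
  } else {
    lambda_robust
  }
  # genomic-control convention: correct inflation, never amplify deflation
  scores$p_adjusted <- adjust_pvalues(scores$p_raw, max(1, lambda))
  attr(scores, "lambda") <- lambda
  attr(scores, "lambda_robust") <- lambda_robust
  attr(scores, "dof") <- dof
  scores
}

#' Call outlier windows under a Bonferroni threshold
#'
#' Flags stretches whose adjusted p-value falls below `alpha` (default
#' `5e-8`, i.e. family-wise 0.05 over roughly one million independent human
#' loci) and groups consecutive significant windows into peaks: a peak is a
#' maximal run of significant stretches at adjacent window positions on the
#' same chromosome.
#'
#' @param pvals A p-value tibble from [score_pvalues()].
#' @param alpha Significance threshold (default `5e-8`).
#' @return A tibble of significant stretches, sorted by position within
#'   chromosome, with a `peak` id column; attributes `alpha`, `n_tested`,
#'   `n_peaks`, `lambda`, `detector`, `feature_set`.
#' @export
call_outliers <- function(pvals, alpha = 5e-8) {
  stopifnot(is.numeric(pvals$p_adjusted))
  hits <- pvals[pvals$p_adjusted < alpha, , drop = FALSE]
  hits <- dplyr::arrange(hits, .data$chrom, .data$center_window)
  if (nrow(hits) > 0L) {
    new_run <- c(TRUE, diff(hits$center_window) != 1L |
                   hits$chrom[-1L] != hits$chrom[-nrow(hits)])
    hits$peak <- cumsum(new_run)
  } else {
    hits$peak <- integer(0)
  }
  attr(hits, "alpha") <- alpha
  attr(hits, "n_tested") <- nrow(pvals)
  attr(hits, "n_peaks") <- if (nrow(hits)) max(hits$peak) else 0L
  for (a in c("lambda", "detector", "feature_set")) {
    attr(hits, a) <- attr(pvals, a)
  }
  hits
}

#' Bonferroni genome-wide threshold
#'
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param n_loci Assumed number of independent loci (default `1e6`, the
#'   standard figure for the human genome in association studies).
#' @return The per-test threshold, `family_alpha / n_loci`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_loci = 1e6) {
  family_alpha / n_loci
}
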