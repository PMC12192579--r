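---
title: "Scanning genomes for anomalous multilocus genotype diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for anomalous multilocus genotype diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgscan)
```

## The problem

Genetic variation along a genome is shaped by biological processes
(mutation, drift, selection, gene flow) and by technical artifacts
(sequencing, mapping and genotyping error).  Most scan methods target one
named process and need a model of it.  `mlgscan` takes the complementary,
model-agnostic view: find genomic regions whose local pattern of variation
is *anomalous* relative to the rest of the genome, whatever the cause, and
hand them to the analyst with calibrated p-values and annotation context.

The scan operates on unphased diploid genotypes at biallelic SNPs — the
form most modern datasets take — encoded per individual as the count of
alternate alleles, $g \in \{0, 1, 2\}$.  The string of these values across
a window of SNPs is the individual's *multilocus genotype* (MLG).

## From genotypes to per-window statistics

For each chromosome the $n \times L$ genotype matrix is slid over with
windows of $\ell$ consecutive SNPs (default $\ell = 51$, stride one SNP).
In each window eight statistics summarise MLG diversity:

* the mean $\mu$, variance $\sigma^2$, skewness $\gamma$ and excess
  kurtosis $\beta$ of the scaled Manhattan distances
  $d(i, i') = \tfrac{1}{\ell} \sum_t |g_{it} - g_{i't}|$ over all
  $\binom{n}{2}$ pairs of individuals, and
* the frequencies $f_1 \ge f_2 \ge f_3 \ge f_4$ of the four most common
  MLG strings.

Moments are population (divide-by-$n$) central moments with excess
kurtosis, the default convention of the scientific stacks this field uses;
zero-variance windows return $\gamma = \beta = 0$ so downstream matrices
stay finite.  Windows are addressed by the base-pair position of their
centre SNP, which is why $\ell$ must be odd.

## Two feature sets over stretches of windows

Local anomalies express themselves over many consecutive windows, so the
unit that receives one anomaly score is a *stretch* of $w$ consecutive
windows (default $w = 129$, stride one window, anchored at its centre
window).  Two feature sets describe a stretch:

* **Moment features** (`moment_features()`): the four moments of each of
  the eight statistics across the $w$ windows — $4 \times 8 = 32$ features.
  These capture the level and shape of each statistic's distribution but
  ignore its ordering along the genome.
* **FDA features** (`fda_features()`): each statistic is treated as a curve
  $f(t)$ over the stretch and represented by ordinary-least-squares
  coefficients on $B = 10$ cubic B-spline basis functions,
  $f(t) \approx \sum_b c_b \phi_b(t)$, plus $B$ coefficients each for the
  re-fitted first and second derivatives of the fitted curve — the
  "velocity" and "acceleration" of diversity.  This gives
  $3 B \times 8 = 240$ features that explicitly model the autocorrelation
  linkage disequilibrium induces along the genome.

Design choices where the design was genuinely open:

* **Knots** are equally spaced on $[1, w]$ ($B - 4$ interior knots), the
  default of standard FDA software; the fit is plain least squares with no
  roughness penalty.
* **Derivative representation.**  "Represented by $B$ basis functions" can
  be realised several ways; we evaluate the analytic derivative of the
  fitted spline at the sample points and re-project onto the same
  $B$-dimensional basis by least squares, which yields exactly $B$
  features per derivative order.  Because both steps are linear, the whole
  240-dimensional feature map is a fixed linear function of the stretch —
  convenient for testing (exact recovery of in-space curves) and fast (one
  matrix product per statistic).
* **No feature standardisation** before the detectors: Mahalanobis
  distance is scale-invariant, and the machine-learning detectors are run
  at library defaults.

## Detectors

Three unsupervised detectors score each feature-matrix row, crossed with
the two feature sets: six methods `MD-M`, `MD-F`, `IF-M`, `IF-F`,
`SVM-M`, `SVM-F`.

**Mahalanobis distance (MD).**
$D^2_i = (x_i - \bar{x})^\top C^{-1} (x_i - \bar{x})$ with the sample mean
and covariance ($N - 1$ denominator).  A practical subtlety: the FDA
derivative blocks are exact linear functions of the fit coefficients, so
the $240 \times 240$ covariance is singular *by construction*; likewise
the MLG-frequency statistics are constant wherever every individual is
unique (the typical neutral configuration), producing constant moment
columns.  `mahalanobis_d2()` therefore supports a rank-truncated
pseudo-inverse: constant columns are dropped, the *correlation* matrix is
eigendecomposed (working on the correlation rather than covariance scale
keeps the truncation scale-equivariant), and components below a relative
tolerance of $10^{-10}$ are discarded.  $D^2$ is then a true Mahalanobis
distance in the column space of $C$ and the effective dimension is the
numerical rank, which is the $p$ used in the F transform below.

**Isolation forest (IF).**  An ensemble (default 100 trees, subsample
256) of random trees that recursively split a random feature at a random
value; anomalous rows are isolated in few splits.  The decision value is
$0.5 - 2^{-\mathbb{E}[h(x)]/c(\psi)}$ with $h$ the path length and
$c(\psi)$ the usual normaliser, so lower = more anomalous.  A seed is
mandatory; scores are deterministic given it.

**One-class SVM.**  RBF kernel with $\gamma = 1/p$ and $\nu = 0.5$
(library defaults), trained by mini-batch because SVM training scales at
least quadratically in $N$.  Rows are partitioned into $m = 18$
non-overlapping batches by systematic sampling (row $r$ goes to batch
$((r - 1) \bmod m) + 1$, so adjacent, LD-correlated stretches land in
different batches) and each row is scored by the model trained on its own
batch; `score_all_batches = TRUE` averages over all batch models instead.

## From scores to calibrated p-values

MD distances are referred to an F distribution via the Hotelling
$T^2$ relation
$F_{p, N-p} = \tfrac{N-p}{p (N-1)} D^2$, with upper-tail p-values.  IF and
SVM scores are first shift-log transformed,
$s' = \log(s - \min s + 10^{-6} \cdot \mathrm{range}(s))$, then treated as
one-dimensional MD scores ($p = 1$).

The F model does not hold exactly — the features are not multivariate
normal and overlapping stretches are strongly autocorrelated — so the
p-value distribution is inflated.  An inflation factor $\lambda$ is
estimated genomic-control style: observed $\chi^2_1$ quantiles of the
p-values are regressed through the origin on expected $\chi^2_1$ quantiles
at plotting positions $(i - 0.5)/N$, the observed quantiles are divided by
$\lambda$, and p-values are recomputed.  Three refinements matter in
practice and are defaults here:

* **Trimming** (`estimate_lambda(trim = 0.1)`): the regression is
  dominated by its largest quantiles — exactly where genuine anomalies
  live.  On a genome with a strong planted anomaly the untrimmed slope can
  reach 30–50, deflating the anomaly's own significance to nothing.  The
  fit therefore excludes the top decile of quantile pairs; under a purely
  scaled null the slope is unchanged by trimming.
* **Two-pass refinement** (`score_pvalues()`): provisional outliers called
  with the robust $\lambda$ are removed and the final $\lambda$ is the
  full regression on the remaining background — the standard
  "genomic control after removing significant loci" practice.
* **Clamping**: the correction is applied only when $\lambda > 1$;
  apparent deflation (e.g. from masking by extreme rows) is never used to
  amplify significance.

Stretches with adjusted $p < \alpha$ are outliers; the default
$\alpha = 0.05 / 10^6 = 5 \times 10^{-8}$ is the family-wise 0.05
threshold over the roughly one million independent loci conventionally
assumed for the human genome.  A *peak* — the paper-level summary unit —
is defined here as a maximal run of significant stretches at consecutive
window positions (the notion is intuitive but rarely formalised; this
definition is the package's).

## Characterising outlier regions

`intersect_annotations()` labels each outlier anchor genic or intergenic
against the longest transcript per gene (ties by file order), with genic
sub-labels assigned at precedence 5′/3′ UTR > exon > intron; coordinates
follow BED half-open 0-based semantics throughout, with the 1-based SNP
positions converted internally.  CRG alignability scores $\le 0.9$ mark
low-confidence regions (inclusive threshold).  Enrichment uses an exact
multinomial test (all outcomes with probability at most the observed
outcome's) for totals up to 500, a $\chi^2$ goodness-of-fit approximation
beyond; two-tailed exact binomial tests use the minimum-likelihood rule.
Because LD correlates adjacent windows, both are calibrated by label
permutation ($10^4$ permutations by default): the permutation p-value is
the fraction of permuted test p-values strictly below the observed one.
`rank_genes()` scores each gene by the minimum adjusted p-value over
outlier windows whose anchor it contains and emits a ranked symbol list
for downstream GO tools.

For visual inspection, `diversity_image()` renders the
$n \times (w + \ell - 1)$ region that defines an outlier data point:
columns are re-polarised to minor-allele counts (per region, flipping
columns whose mean exceeds 1; ties unflipped), each of the $w$ windows is
row-sorted by L1 norm (stable sort), and each pixel is the mean sorted
value over the windows covering that SNP.  Dark pixels are homozygous
major, bright homozygous minor, intermediate heterozygous.

## What the synthetic generator emulates — and what it does not

`simulate_genotypes()` draws per-site alternate-allele frequencies
uniformly from $[0.05, 0.5]$ and builds two pseudo-haplotypes per
individual in which each allele is Bernoulli with the site frequency
except that, with probability $\rho$ (default 0.5), it copies the previous
site's allele on the same haplotype.  This first-order copying process
produces the one feature the FDA machinery needs from real data — local
autocorrelation of diversity — with none of the rest: no recombination
map, no demography, no coalescent genealogy, no site-frequency-spectrum
realism.  Tests passing on it show the pipeline's plumbing and calibration
behave as designed; they do not show field performance on real genomes.

`inject_anomaly()` plants three archetypes: `excess_het` (heterozygote
probability 0.9, a balancing-selection-like signal), `freq_collapse`
(every individual carries one of two fixed MLG strings at 0.5/0.5 — the
strings are drawn from the background site-frequency law so the anomaly is
a pure collapse of MLG diversity, not an allele-frequency shift) and
`dropout_artifact` (30% of individuals forced homozygous reference, a
technical-artifact signature).  Magnitudes are deliberately large so power
checks are robust at desk scale.

The test and example scale — $n = 60$ individuals, $L = 6000$ SNPs,
one planted 400-SNP collapse — was chosen so a full two-genome scan with
both feature sets completes in well under a minute while every stage still
has realistic dimensions ($5822$ stretches, $32$- and $240$-column feature
matrices).  At this scale the planted region spans roughly 10% of all
stretches, which is precisely what motivated the robust two-pass
$\lambda$; on a whole genome the anomalous fraction is far smaller.

## Numerical choices and degenerate inputs

* Variance below $100 \, \epsilon \, (|\mu| + 1)^2$ counts as zero when
  computing skewness/kurtosis (returns 0, not NaN).
* p-values that underflow are floored at `.Machine$double.xmin`; p-values
  of exactly 1 are clamped to $1 - 1/(2N)$ before $\chi^2$ quantile
  mapping.
* Eigenvalues below $10^{-10}$ of the largest are truncated in the
  pseudo-inverse; the low-level `mahalanobis_d2()` defaults to erroring on
  singular covariance and names the flag to switch.
* Ties in the L1 row sort and in minor-allele polarisation are resolved by
  stability (original order kept, tied columns unflipped).
* Sites with any missing genotype call are dropped at VCF load (count
  reported), so every window is a complete $\{0,1,2\}$ matrix.

## Known limitations

* The neutral false-call rate of `MD-M` at $\alpha = 5 \times 10^{-8}$
  fluctuates around one per thousand stretches at desk scale: moment
  features are genuinely heavier-tailed than the F model, and a single
  scale factor $\lambda$ cannot fix a tail-shape mismatch.  `MD-F` is much
  better calibrated — the spline representation absorbs local trends — and
  is the recommended default, consistent with its behaviour on real data.
* Isolation-forest subsampling is tied to row indices, so scores are
  seed-reproducible but not row-permutation-equivariant.
* libsvm training depends slightly on data order; SVM scores are
  deterministic for identical input but only numerically (not bitwise)
  equivariant under row permutation.
* Annotation assignment uses the anchor position only; a stretch spanning
  several annotation classes contributes one label.

## A worked example

```{r example, eval = FALSE}
library(mlgscan)

genome <- simulate_genotypes(n = 60, n_snps = 6000, ld_rho = 0.5, seed = 1)
genome <- inject_anomaly(genome, 2801:3200, "freq_collapse", seed = 2)

cfg <- scan_config(methods = c("MD-M", "MD-F", "IF-M", "IF-F"), seed = 1)
scan <- mlg_scan(genome, cfg)
glance(scan)
autoplot(scan)

hits <- scan$calls[["MD-F"]]
img <- diversity_image(
  stretch_region(genome, hits$stretch[which.min(hits$p_adjusted)]),
  label = "top MD-F outlier")
plot_diversity_image(img)
```
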