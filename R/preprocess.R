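#' Median-of-ratios size factors for a count matrix
#'
#' The classical RNA-seq normalization: for each sample, the factor is the
#' median over features of the ratio of the sample's count to the feature's
#' geometric mean across samples, restricted to features with a positive
#' geometric mean (i.e. expressed in every sample). After division by the
#' factors, samples that differ only by a scalar library-size multiple
#' coincide.
#'
#' @param counts An [omics_matrix()] of kind `"transcriptome"`, or a bare
#'   non-negative count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "omics_matrix")) counts$values else counts
  if (any(m < 0)) stop("counts must be non-negative")
  loggeo <- rowMeans(log(m))        # -Inf where any sample has a zero
  use <- is.finite(loggeo)
  if (!any(use))
    stop("normalization failure: no feature expressed in all samples")
  sf <- apply(m[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("normalization failure: non-positive size factor")
  sf
}

#' Log2 transform with a pseudo-count
#'
#' `log2(x + pseudo)` elementwise; `NA` entries stay `NA`. The proteome
#' stage uses `pseudo = 5` on normalized spectrum values; the transcriptome
#' stage uses `pseudo = 1` on size-factor-normalized counts.
#'
#' @param m Numeric matrix with non-negative (or missing) entries.
#' @param pseudo Positive offset added before the log.
#' @return Matrix of the same shape.
#' @export
log_with_pseudocount <- function(m, pseudo = 5) {
  if (any(m < 0, na.rm = TRUE)) stop("values must be non-negative")
  if (pseudo <= 0 && any(m == 0, na.rm = TRUE))
    stop("pseudo must be positive when zeros are present")
  log2(m + pseudo)
}

#' Compound-minimum imputation for left-censored metabolites
#'
#' Every missing entry of a compound (row) is replaced by the minimum
#' observed value of that compound — the standard treatment when missing
#' values are assumed to lie below the detection limit. Fully missing
#' compounds cannot be imputed; they are dropped with a warning and listed
#' in the `dropped` attribute.
#'
#' @param metabolome An [omics_matrix()] of kind `"metabolome"`.
#' @return The imputed [omics_matrix()] (no missing values; mask cleared),
#'   with attribute `dropped` naming any unimputable compounds.
#' @export
impute_compound_minimum <- function(metabolome) {
  stopifnot(inherits(metabolome, "omics_matrix"))
  v <- metabolome$values
  all_missing <- rowSums(!is.na(v)) == 0
  dropped <- rownames(v)[all_missing]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " compound(s) with no observed values: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    v <- v[!all_missing, , drop = FALSE]
  }
  row_min <- apply(v, 1, min, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- row_min[idx[, 1]]
  out <- omics_matrix(v, metabolome$omic_kind, metabolome$group,
                      batch = metabolome$batch)
  attr(out, "dropped") <- dropped
  out
}

#' Per-feature batch mean-centering
#'
#' For each feature, subtracts every batch's mean and adds back the grand
#' mean, removing additive batch location effects on the log scale while
#' leaving group composition untouched. With a single batch this is the
#' identity; it is idempotent (a projection).
#'
#' @param logmatrix Numeric matrix on the log scale, features x samples.
#' @param batch Character vector of batch labels, one per column.
#' @return Matrix of the same shape.
#' @export
batch_center <- function(logmatrix, batch) {
  if (length(batch) != ncol(logmatrix))
    stop("invalid batch labels: need one per sample")
  if (anyNA(batch)) stop("invalid batch labels: NA present")
  batch <- as.character(batch)
  grand <- rowMeans(logmatrix)
  out <- logmatrix
  for (b in unique(batch)) {
    j <- batch == b
    out[, j] <- logmatrix[, j, drop = FALSE] -
      rowMeans(logmatrix[, j, drop = FALSE]) + grand
  }
  out
}

#' Top-k most variable features
#'
#' Features ranked by sample variance (n - 1 denominator), largest first;
#' ties broken by feature id in lexicographic order so the selection is
#' deterministic.
#'
#' @param m Numeric matrix with feature row names.
#' @param k Number of features to return (default 500, capped at
#'   `nrow(m)`).
#' @return Character vector of feature ids, variance-sorted.
#' @export
top_variable_features <- function(m, k = 500) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(m))
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m), method = "radix")
  rownames(m)[ord][seq_len(k)]
}

#' Top-k most expressed features
#'
#' Alternative selection ranked by mean abundance instead of variance
#' (same tie-breaking); provided for comparison, with no claim that it
#' better isolates group structure.
#'
#' @inheritParams top_variable_features
#' @return Character vector of feature ids, mean-sorted.
#' @export
top_expressed_features <- function(m, k = 500) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(m))
  mu <- rowMeans(m)
  ord <- order(-mu, rownames(m), method = "radix")
  rownames(m)[ord][seq_len(k)]
}

#' Row-wise z-scaling
#'
#' Centers every row to mean 0 and scales to sample standard deviation 1;
#' constant rows (sd = 0) map to all-zeros rather than NaN.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape.
#' @export
row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Standard pre-test transform for one omic
#'
#' Applies each omic's canonical preparation ahead of differential testing
#' or projection: transcriptome counts are divided by median-of-ratios size
#' factors and log2-transformed with pseudo-count 1; proteome intensities
#' are log2-transformed with pseudo-count 5 (batch handling is left to the
#' test's covariate or to [batch_center()] for PCA); metabolome abundances
#' are compound-minimum imputed and log2-transformed.
#'
#' @param om An [omics_matrix()].
#' @return A list with `logvalues` (features x samples log2 matrix) and the
#'   possibly updated `omics` object.
#' @export
pretest_transform <- function(om) {
  stopifnot(inherits(om, "omics_matrix"))
  switch(om$omic_kind,
    transcriptome = {
      sf <- size_factors_median_of_ratios(om)
      lv <- log_with_pseudocount(sweep(om$values, 2, sf, "/"), pseudo = 1)
      list(logvalues = lv, omics = om)
    },
    proteome = {
      lv <- log_with_pseudocount(om$values, pseudo = 5)
      list(logvalues = lv, omics = om)
    },
    metabolome = {
      imp <- impute_compound_minimum(om)
      lv <- log_with_pseudocount(imp$values, pseudo = 1)
      list(logvalues = lv, omics = imp)
    }
  )
}
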