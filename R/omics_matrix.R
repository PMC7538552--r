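#' Omics abundance matrix with sample metadata
#'
#' A light container for one omic layer: a features-by-samples numeric
#' matrix plus the sample annotation the downstream stages need (two-level
#' group factor, optional batch labels) and an explicit missingness mask.
#' Transcriptome values are raw counts; proteome values are normalized
#' spectrum intensities; metabolome values are normalized abundances in
#' which `NA` marks below-detection-limit entries.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row and column names are required and must be unique.
#' @param omic_kind One of `"transcriptome"`, `"proteome"`, `"metabolome"`.
#' @param group Character or factor of length `ncol(values)` with exactly
#'   two levels; the *second* level (alphabetical, or factor order) is the
#'   treated group, so log fold changes read treated minus control.
#' @param batch Optional character vector of batch labels per sample.
#' @param mask Optional logical matrix of the same shape as `values`,
#'   `TRUE` where the entry is missing. Defaults to `is.na(values)`.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `feature_ids`, `sample_ids`, `omic_kind`, `group`, `batch`,
#'   `mask`.
#' @export
omics_matrix <- function(values, omic_kind, group, batch = NULL, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("feature and sample ids must be unique")
  omic_kind <- match.arg(omic_kind, c("transcriptome", "proteome", "metabolome"))
  group <- as.factor(group)
  if (length(group) != ncol(values))
    stop("`group` must have one label per sample")
  if (nlevels(droplevels(group)) != 2L)
    stop("`group` must have exactly two levels")
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != ncol(values))
      stop("`batch` must have one label per sample")
    if (anyNA(batch))
      stop("missing batch label")
  }
  if (is.null(mask)) mask <- is.na(values)
  if (!identical(dim(mask), dim(values)))
    stop("`mask` must match the shape of `values`")
  obs <- values[!mask]
  if (omic_kind != "metabolome" && any(is.na(values)))
    stop("missing values are only allowed in the metabolome")
  if (any(obs < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  if (omic_kind == "transcriptome" && any(obs != round(obs)))
    stop("transcriptome values must be integer counts")
  structure(
    list(
      values = values,
      feature_ids = rownames(values),
      sample_ids = colnames(values),
      omic_kind = omic_kind,
      group = stats::setNames(group, colnames(values)),
      batch = if (is.null(batch)) NULL else stats::setNames(batch, colnames(values)),
      mask = mask
    ),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix [%s]: %d features x %d samples (%s)\n",
    x$omic_kind, nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", levels(x$group), table(x$group)), collapse = ", ")
  ))
  if (!is.null(x$batch))
    cat("  batches:", paste(unique(x$batch), collapse = ", "), "\n")
  if (any(x$mask))
    cat(sprintf("  missing: %d / %d entries (%.1f%%)\n",
                sum(x$mask), length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# Control / treated levels in the order logFC is computed (treated - control).
group_levels <- function(om) levels(om$group)
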