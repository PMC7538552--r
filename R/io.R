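#' Write / read an omics matrix in the pipeline's TSV dialect
#'
#' Matrices are written as TSV with the feature id in the first column
#' (header `feature_id`) and one column per sample; sample metadata goes in
#' a companion TSV with columns `sample_id`, `group` and (optionally)
#' `batch`. Missing metabolome entries are written as `NA`.
#'
#' @param om An [omics_matrix()].
#' @param path Matrix TSV path.
#' @param meta_path Metadata TSV path; default replaces the extension with
#'   `.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(om, path, meta_path = sub("\\.tsv$", ".meta.tsv", path)) {
  stopifnot(inherits(om, "omics_matrix"))
  df <- data.frame(feature_id = om$feature_ids, om$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = om$sample_ids,
                     group = as.character(om$group),
                     stringsAsFactors = FALSE)
  if (!is.null(om$batch)) meta$batch <- om$batch
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @param omic_kind Omic kind of the matrix being read.
#' @export
read_omics_tsv <- function(path, omic_kind,
                           meta_path = sub("\\.tsv$", ".meta.tsv", path)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(vals), meta$sample_id), ]
  omics_matrix(vals, omic_kind, meta$group,
               batch = if ("batch" %in% names(meta)) meta$batch else NULL)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member ids.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return For the reader, a named list of member-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Read and write compartment annotation TSVs
#'
#' Two columns, `feature_id` and `compartment_id`; a feature may appear on
#' several rows (multi-membership).
#'
#' @param compartments Named list of feature-id vectors.
#' @param path File path.
#' @export
write_compartments_tsv <- function(compartments, path) {
  df <- data.frame(
    feature_id = unlist(compartments, use.names = FALSE),
    compartment_id = rep(names(compartments), lengths(compartments)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compartments_tsv
#' @export
read_compartments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$feature_id, df$compartment_id)
}

#' Serialize ground truth as a JSON sidecar
#'
#' @param truth A [ground_truth()] object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(lapply(unclass(truth), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path)
  num <- function(el) {
    if (!length(el)) return(numeric())
    stats::setNames(vapply(el, as.numeric, numeric(1)), names(el))
  }
  chr <- function(el) {
    if (!length(el)) return(character())
    stats::setNames(vapply(el, as.character, character(1)), names(el))
  }
  ground_truth(
    de_genes = num(x$de_genes), de_proteins = num(x$de_proteins),
    de_metabolites = num(x$de_metabolites),
    pathway_direction = chr(x$pathway_direction),
    enriched_compartments = num(x$enriched_compartments),
    batch_offsets = num(x$batch_offsets)
  )
}

#' Write a differential-expression table as TSV
#'
#' Columns: `feature_id`, `logFC`, `p`, `fdr`, `is_de`, `direction`.
#'
#' @param de A `de_table` data frame from [de_test()].
#' @param path TSV path.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(
    de[, c("feature_id", "logFC", "p", "fdr", "is_de", "direction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
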