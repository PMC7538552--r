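#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run. Defaults are the pipeline's
#' canonical constants: dual DE threshold FDR < 0.05 with |logFC| > 0.5,
#' enrichment significance FDR < 0.1, 1000 resampling draws for the
#' compartment test, 1000 permutations for GSEA, top 500 variable features
#' for PCA.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; per-stage streams are derived from it, with
#'   optional per-stage overrides in `stage_seeds` (named list).
#' @param simulate Generate the synthetic inputs (default TRUE). When
#'   FALSE, `inputs` must name existing files: `transcriptome`,
#'   `proteome`, `metabolome` (matrix TSVs with `.meta.tsv` companions),
#'   `gene_sets` (GMT), `compartments` (TSV), `graph` (TSV).
#' @param n_genes,n_proteins,n_metabolites,n_pathways,n_compartments
#'   Synthetic universe sizes.
#' @param n_per_group Named list of per-omic group sizes.
#' @param fdr_de,lfc,fdr_gsea Thresholds.
#' @param B,n_perm,k_variable Resampling, permutation and feature-selection
#'   sizes.
#' @param truth_args Extra arguments passed to [plant_truth()] (e.g.
#'   planted pathways and compartment weights).
#' @param inputs Named list of input paths when `simulate = FALSE`.
#' @param stage_seeds Named list of per-stage seed overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("triomics_run_"), seed = 1,
                       simulate = TRUE,
                       n_genes = 1000, n_proteins = 400, n_metabolites = 200,
                       n_pathways = 30, n_compartments = 7,
                       n_per_group = list(transcriptome = 5, proteome = 4,
                                          metabolome = 5),
                       fdr_de = 0.05, lfc = 0.5, fdr_gsea = 0.1,
                       B = 1000, n_perm = 1000, k_variable = 500,
                       truth_args = list(
                         n_de_genes = 60, n_de_metabolites = 40,
                         effect_size = 2,
                         pathways_up = c("pathway_01", "pathway_02"),
                         pathways_down = "pathway_03",
                         compartment_weights = c(compartment_01 = 4),
                         batch_offsets = c(b1 = 0, b2 = 1)
                       ),
                       inputs = list(), stage_seeds = list()) {
  stopifnot(fdr_de > 0, fdr_de < 1, fdr_gsea > 0, fdr_gsea < 1,
            lfc >= 0, B >= 100, n_perm >= 100, k_variable >= 1)
  structure(
    list(out_dir = out_dir, seed = seed, simulate = simulate,
         n_genes = n_genes, n_proteins = n_proteins,
         n_metabolites = n_metabolites, n_pathways = n_pathways,
         n_compartments = n_compartments, n_per_group = n_per_group,
         fdr_de = fdr_de, lfc = lfc, fdr_gsea = fdr_gsea,
         B = B, n_perm = n_perm, k_variable = k_variable,
         truth_args = truth_args, inputs = inputs,
         stage_seeds = stage_seeds),
    class = "run_config"
  )
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

stage_seed_for <- function(config, stage) {
  if (!is.null(config$stage_seeds[[stage]])) config$stage_seeds[[stage]]
  else config$seed
}

#' Per-omic DE tally
#'
#' The "k of m" summary: DE count, total tested, percentage (one decimal),
#' and the up/down split by logFC sign.
#'
#' @param de A `de_table`.
#' @return Named list `n_de`, `n_total`, `percent`, `n_up`, `n_down`.
#' @export
tally_de <- function(de) {
  n_de <- sum(de$is_de)
  n_total <- nrow(de)
  list(
    n_de = n_de, n_total = n_total,
    percent = round(100 * n_de / max(n_total, 1L), 1),
    n_up = sum(de$is_de & de$logFC > 0),
    n_down = sum(de$is_de & de$logFC < 0)
  )
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full tri-omics pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> per-omic differential
#' expression -> preranked GSEA per omic -> cross-omics consensus ->
#' compartment association tests (DE genes and DE proteins) -> metabolic
#' map painting -> per-omic PCA. All outputs are written under
#' `config$out_dir` as TSV/GMT/JSON and a manifest with input hashes and
#' the seeds actually used; re-running with the same config and seed
#' reproduces the outputs byte for byte.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return A `run_report` list: `tallies` (per-omic DE tallies), `de`
#'   (tables), `gsea`, `consensus`, `venn`, `compartments` (gene and
#'   protein results), `paint` (summary), `pca` (per-omic variance
#'   explained and PC1 silhouette), `truth` (when simulated), `manifest`.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- if (quiet) function(...) invisible() else pipeline_log
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    log_("simulate", sprintf("universe %d genes / %d proteins / %d metabolites, seed %d",
                             config$n_genes, config$n_proteins,
                             config$n_metabolites, config$seed))
    uni <- generate_universe(config$n_genes, config$n_proteins,
                             config$n_metabolites, config$n_pathways,
                             config$n_compartments,
                             seed = stage_seed_for(config, "universe"))
    truth <- do.call(plant_truth, c(list(universe = uni,
                                         seed = stage_seed_for(config, "truth")),
                                    config$truth_args))
    rna <- simulate_transcriptome(truth, uni,
                                  n_per_group = config$n_per_group$transcriptome,
                                  seed = stage_seed_for(config, "transcriptome"))
    prot <- simulate_proteome(truth, uni,
                              n_per_group = config$n_per_group$proteome,
                              seed = stage_seed_for(config, "proteome"))
    met <- simulate_metabolome(truth, uni,
                               n_per_group = config$n_per_group$metabolome,
                               seed = stage_seed_for(config, "metabolome"))
    gene_sets <- uni$gene_sets
    compartments <- uni$compartments
    graph <- uni$reaction_graph
    gene_universe <- uni$genes
    protein_universe <- uni$proteins
    write_omics_tsv(rna, out("transcriptome.tsv"))
    write_omics_tsv(prot, out("proteome.tsv"))
    write_omics_tsv(met, out("metabolome.tsv"))
    write_gmt(gene_sets, out("gene_sets.gmt"))
    write_compartments_tsv(compartments, out("compartments.tsv"))
    write_pathway_graph(graph, out("reaction_graph.tsv"))
    write_ground_truth(truth, out("ground_truth.json"))
  } else {
    need <- c("transcriptome", "proteome", "metabolome", "gene_sets",
              "compartments", "graph")
    missing_in <- setdiff(need, names(config$inputs))
    if (length(missing_in))
      stop("missing input(s): ", paste(missing_in, collapse = ", "))
    for (p in unlist(config$inputs[need]))
      if (!file.exists(p)) stop("missing input file: ", p)
    log_("load", "reading input matrices and annotations")
    rna <- read_omics_tsv(config$inputs$transcriptome, "transcriptome")
    prot <- read_omics_tsv(config$inputs$proteome, "proteome")
    met <- read_omics_tsv(config$inputs$metabolome, "metabolome")
    gene_sets <- read_gmt(config$inputs$gene_sets)
    compartments <- read_compartments_tsv(config$inputs$compartments)
    graph <- read_pathway_graph(config$inputs$graph)
    gene_universe <- rna$feature_ids
    protein_universe <- prot$feature_ids
  }

  # --- differential expression -------------------------------------------
  log_("de", "moderated-t tests per omic")
  de <- list(
    transcriptome = de_test(rna, config$fdr_de, config$lfc),
    proteome = de_test(prot, config$fdr_de, config$lfc),
    metabolome = de_test(met, config$fdr_de, config$lfc)
  )
  for (k in names(de)) write_de_tsv(de[[k]], out(paste0("de_", k, ".tsv")))
  tallies <- lapply(de, tally_de)
  for (k in names(tallies))
    log_("de", sprintf("%s: %d of %d DE (%.1f%%; %d up / %d down)", k,
                       tallies[[k]]$n_de, tallies[[k]]$n_total,
                       tallies[[k]]$percent, tallies[[k]]$n_up,
                       tallies[[k]]$n_down))

  # --- enrichment and consensus ------------------------------------------
  log_("gsea", sprintf("preranked GSEA, %d permutations", config$n_perm))
  gsea <- list(
    transcriptome = preranked_gsea(rank_metric(de$transcriptome), gene_sets,
                                   n_perm = config$n_perm,
                                   seed = stage_seed_for(config, "gsea"),
                                   fdr_cut = config$fdr_gsea),
    proteome = preranked_gsea(rank_metric(de$proteome), gene_sets,
                              n_perm = config$n_perm,
                              seed = stage_seed_for(config, "gsea") + 1,
                              fdr_cut = config$fdr_gsea)
  )
  for (k in names(gsea))
    utils::write.table(gsea[[k]], out(paste0("gsea_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- cross_omics_consensus(gsea$transcriptome, gsea$proteome,
                                fdr_cut = config$fdr_gsea)
  utils::write.table(cons$consensus, out("consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_("consensus", sprintf("%d common pathway(s)", nrow(cons$consensus)))

  # --- compartment association -------------------------------------------
  log_("compartments", sprintf("resampling test, B = %d", config$B))
  comp <- list(
    genes = bootstrap_compartment_test(de_sets(de$transcriptome)$all,
                                       gene_universe, compartments,
                                       B = config$B,
                                       seed = stage_seed_for(config, "bootstrap")),
    proteins = bootstrap_compartment_test(de_sets(de$proteome)$all,
                                          protein_universe, compartments_restricted(
                                            compartments, protein_universe),
                                          B = config$B,
                                          seed = stage_seed_for(config, "bootstrap") + 1)
  )
  for (k in names(comp))
    utils::write.table(comp[[k]], out(paste0("compartments_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- painting ----------------------------------------------------------
  log_("paint", "painting the reaction graph")
  dg <- de_direction_map(de$transcriptome)
  dp <- de_direction_map(de$proteome)
  dm <- de$metabolome[de$metabolome$is_de, ]
  edge_states <- paint_edges(graph, dg, dp, gene_universe, protein_universe)
  node_states <- paint_nodes(graph, stats::setNames(dm$logFC, dm$feature_id))
  write_paint_tsv(edge_states, node_states, out("paint.tsv"))
  paint_summary <- summarize_painting(edge_states, node_states)

  # --- PCA ---------------------------------------------------------------
  log_("pca", sprintf("top %d variable features (all metabolites)", config$k_variable))
  pca_res <- list(
    transcriptome = pca_stage(pretest_transform(rna)$logvalues, rna$group,
                              config$k_variable),
    proteome = {
      pv <- pretest_transform(prot)$logvalues
      if (!is.null(prot$batch)) pv <- batch_center(pv, prot$batch)
      pca_stage(pv, prot$group, config$k_variable)
    },
    metabolome = pca_stage(pretest_transform(met)$logvalues, met$group,
                           k = NULL)
  )

  # --- manifest ----------------------------------------------------------
  files <- list.files(config$out_dir, pattern = "\\.(tsv|gmt|json)$",
                      full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("triomics")),
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = c(
      "universe", "truth", "transcriptome", "proteome", "metabolome",
      "gsea", "bootstrap")), function(s) stage_seed_for(config, s)),
    thresholds = list(fdr_de = config$fdr_de, lfc = config$lfc,
                      fdr_gsea = config$fdr_gsea),
    B = config$B, n_perm = config$n_perm, k_variable = config$k_variable,
    files = as.list(tools::md5sum(files))
  )
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  structure(
    list(tallies = tallies, de = de, gsea = gsea,
         consensus = cons$consensus, venn = cons$venn,
         compartments = comp, paint = paint_summary, pca = pca_res,
         truth = truth, manifest = manifest, out_dir = config$out_dir),
    class = "run_report"
  )
}

# DE direction lookup (feature -> up/down) for painting
de_direction_map <- function(de) {
  d <- de[de$is_de, ]
  stats::setNames(d$direction, d$feature_id)
}

# restrict compartment membership to a feature universe, dropping emptied
# compartments
compartments_restricted <- function(compartments, universe) {
  r <- lapply(compartments, intersect, y = universe)
  r[lengths(r) > 0]
}

pca_stage <- function(logvalues, group, k) {
  feats <- if (is.null(k)) rownames(logvalues)
           else top_variable_features(logvalues, k)
  pc <- pca(logvalues[feats, , drop = FALSE],
            n_components = min(3, ncol(logvalues)))
  list(variance_explained = pc$variance_explained,
       pc1_silhouette = silhouette_1d(pc$scores[, 1], group),
       scores = pc$scores)
}

#' @export
print.run_report <- function(x, ...) {
  cat("triomics run report\n")
  for (k in names(x$tallies)) {
    t <- x$tallies[[k]]
    cat(sprintf("  %-13s %4d of %5d DE (%5.1f%%; %d up / %d down)\n",
                k, t$n_de, t$n_total, t$percent, t$n_up, t$n_down))
  }
  cat(sprintf("  consensus pathways: %d\n", nrow(x$consensus)))
  sig <- x$compartments$genes
  sig <- sig$compartment_id[sig$p_emp < 0.05]
  cat(sprintf("  compartments with p_emp < 0.05 (genes): %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  cat(sprintf("  painted edges: %s\n",
              paste(sprintf("%s=%d", names(x$paint$edges), x$paint$edges),
                    collapse = " ")))
  invisible(x)
}
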