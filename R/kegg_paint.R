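#' Read / write a metabolic reaction graph
#'
#' Edge-list TSV with columns `reaction_id`, `substrate`, `product`,
#' `evidence`; evidence is a semicolon-separated list of feature ids
#' carrying a `g:` (gene) or `p:` (protein) namespace prefix. Nodes are
#' the metabolites appearing as substrates or products.
#'
#' @param graph Data frame in the schema above.
#' @param path TSV path.
#' @export
write_pathway_graph <- function(graph, path) {
  utils::write.table(graph[, c("reaction_id", "substrate", "product", "evidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathway_graph
#' @export
read_pathway_graph <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

# split "g:x;p:y" into a data.frame of (namespace, feature)
parse_evidence <- function(ev) {
  toks <- strsplit(ev, ";", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  ns <- substr(toks, 1, 2)
  if (any(!ns %in% c("g:", "p:")))
    stop("invalid graph: evidence must use g:/p: prefixes, got ",
         toks[!ns %in% c("g:", "p:")][1])
  data.frame(namespace = substr(toks, 1, 1), feature = substring(toks, 3),
             stringsAsFactors = FALSE)
}

#' Paint reaction edges from gene/protein DE directions
#'
#' Each edge collects the directions of its DE evidence features (genes
#' against `de_genes`, proteins against `de_proteins`); every DE feature
#' is one vote and only the direction of change is consulted, never the
#' magnitude. All votes up gives `up_red`, all down gives `down_blue`,
#' mixed gives `conflict_purple`, and no DE evidence leaves the edge
#' `unpainted`.
#'
#' @param graph Reaction-graph data frame (see [read_pathway_graph()]).
#' @param de_genes,de_proteins Named character vectors mapping DE feature
#'   ids to `"up"`/`"down"` (e.g. built from [de_sets()]).
#' @param gene_universe,protein_universe Optional id universes; evidence
#'   features outside them raise an invalid-graph error.
#' @return Data frame `reaction_id`, `substrate`, `product`, `state` with
#'   state in `{up_red, down_blue, conflict_purple, unpainted}`.
#' @export
paint_edges <- function(graph, de_genes, de_proteins,
                        gene_universe = NULL, protein_universe = NULL) {
  if (length(de_genes) && !all(de_genes %in% c("up", "down")))
    stop("DE directions must be 'up' or 'down'")
  if (length(de_proteins) && !all(de_proteins %in% c("up", "down")))
    stop("DE directions must be 'up' or 'down'")
  states <- vapply(seq_len(nrow(graph)), function(i) {
    ev <- parse_evidence(graph$evidence[i])
    if (!is.null(gene_universe)) {
      miss <- ev$feature[ev$namespace == "g" & !(ev$feature %in% gene_universe)]
      if (length(miss)) stop("invalid graph: unknown gene ", miss[1])
    }
    if (!is.null(protein_universe)) {
      miss <- ev$feature[ev$namespace == "p" & !(ev$feature %in% protein_universe)]
      if (length(miss)) stop("invalid graph: unknown protein ", miss[1])
    }
    dirs <- c(
      unname(de_genes[ev$feature[ev$namespace == "g"]]),
      unname(de_proteins[ev$feature[ev$namespace == "p"]])
    )
    dirs <- dirs[!is.na(dirs)]
    if (!length(dirs)) "unpainted"
    else if (all(dirs == "up")) "up_red"
    else if (all(dirs == "down")) "down_blue"
    else "conflict_purple"
  }, character(1))
  data.frame(reaction_id = graph$reaction_id, substrate = graph$substrate,
             product = graph$product, state = states,
             stringsAsFactors = FALSE)
}

#' Paint metabolite nodes with a fold-change gradient
#'
#' DE metabolites are colored by direction (`up_red` / `down_blue`) with
#' an intensity gradient `min(|logFC|, cap) / cap`; non-DE metabolites
#' stay `unpainted` with no gradient regardless of their fold change.
#'
#' @param graph Reaction-graph data frame; nodes are its substrates and
#'   products.
#' @param de_metabolites Named numeric vector of log2 fold changes for DE
#'   metabolites only.
#' @param cap Gradient saturation point on |logFC| (default 3, > 0).
#' @return Data frame `metabolite_id`, `state`, `intensity` (`NA` for
#'   unpainted nodes).
#' @export
paint_nodes <- function(graph, de_metabolites, cap = 3) {
  if (cap <= 0) stop("cap must be positive")
  nodes <- sort(unique(c(graph$substrate, graph$product)))
  lfc <- de_metabolites[nodes]
  state <- ifelse(is.na(lfc), "unpainted",
                  ifelse(lfc > 0, "up_red", "down_blue"))
  intensity <- ifelse(is.na(lfc), NA_real_, pmin(abs(lfc), cap) / cap)
  data.frame(metabolite_id = nodes, state = state, intensity = intensity,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally a painted graph
#'
#' @param edge_states Output of [paint_edges()].
#' @param node_states Output of [paint_nodes()].
#' @return List with `edges` and `nodes` named count vectors covering all
#'   states (counts partition the elements).
#' @export
summarize_painting <- function(edge_states, node_states) {
  edge_levels <- c("up_red", "down_blue", "conflict_purple", "unpainted")
  node_levels <- c("up_red", "down_blue", "unpainted")
  list(
    edges = table(factor(edge_states$state, levels = edge_levels)),
    nodes = table(factor(node_states$state, levels = node_levels))
  )
}

#' Write a paint table as TSV
#'
#' Long format: `element_id`, `element_type` (edge/node), `state`,
#' `intensity` (empty for edges and unpainted nodes).
#'
#' @param edge_states,node_states Painted edges and nodes.
#' @param path TSV path.
#' @export
write_paint_tsv <- function(edge_states, node_states, path) {
  df <- rbind(
    data.frame(element_id = edge_states$reaction_id, element_type = "edge",
               state = edge_states$state, intensity = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(element_id = node_states$metabolite_id, element_type = "node",
               state = node_states$state, intensity = node_states$intensity,
               stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
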