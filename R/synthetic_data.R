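# One RNG stream per consumer, derived from a master seed, so each omic can
# be regenerated independently of the others.
STREAM_OFFSETS <- c(
  universe = 0L, truth = 1L, transcriptome = 2L, proteome = 3L,
  metabolome = 4L, gsea = 5L, bootstrap = 6L, pipeline = 7L
)

#' Derive a per-stream seed from a master seed
#'
#' @param master Integer master seed.
#' @param stream Stream name, one of `names(STREAM_OFFSETS)`.
#' @return A positive integer seed, distinct across streams.
#' @keywords internal
stream_seed <- function(master, stream) {
  stream <- match.arg(stream, names(STREAM_OFFSETS))
  off <- STREAM_OFFSETS[[stream]]
  as.integer((as.numeric(master) * 8191 + off * 524287 + 1) %% 2147483629)
}

#' Ground truth for a simulated tri-omics experiment
#'
#' Records what was planted so downstream stages can be scored against it:
#' per-omic DE features with their log2 effect sizes, the intended
#' direction of each pathway, compartment selection weights, and per-batch
#' log-scale offsets for the proteome.
#'
#' @param de_genes,de_proteins,de_metabolites Named numeric vectors of
#'   planted log2 effects (name = feature id). Empty vectors mean a null
#'   omic.
#' @param pathway_direction Named character vector over pathway ids with
#'   values `"up"`, `"down"` or `"null"`.
#' @param enriched_compartments Named numeric vector of selection-weight
#'   multipliers (>= 1); multiplier 1 means no planted enrichment.
#' @param batch_offsets Named numeric vector of additive log2-scale shifts
#'   per proteome batch.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(de_genes = numeric(), de_proteins = numeric(),
                         de_metabolites = numeric(),
                         pathway_direction = character(),
                         enriched_compartments = numeric(),
                         batch_offsets = numeric()) {
  for (v in list(de_genes, de_proteins, de_metabolites, batch_offsets))
    if (length(v) && (!is.numeric(v) || any(!is.finite(v)) || is.null(names(v))))
      stop("planted effects must be finite named numeric vectors")
  if (length(pathway_direction) &&
      !all(pathway_direction %in% c("up", "down", "null")))
    stop("pathway_direction values must be up/down/null")
  if (length(enriched_compartments) && any(enriched_compartments < 1))
    stop("compartment enrichment multipliers must be >= 1")
  structure(
    list(
      de_genes = de_genes, de_proteins = de_proteins,
      de_metabolites = de_metabolites,
      pathway_direction = pathway_direction,
      enriched_compartments = enriched_compartments,
      batch_offsets = batch_offsets
    ),
    class = "ground_truth"
  )
}

#' Generate a synthetic annotation universe
#'
#' Builds the fixed annotation scaffolding of a tri-omics experiment:
#' feature id universes for the three omics (proteins are the products of a
#' random subset of the genes and share their ids, so gene sets apply to
#' both layers), KEGG-like gene sets, Human-Protein-Atlas-like overlapping
#' subcellular compartments, and a metabolic reaction graph whose edges
#' carry gene/protein evidence.
#'
#' @param n_genes,n_proteins,n_metabolites,n_pathways,n_compartments
#'   Positive counts. `n_proteins <= n_genes` is required.
#' @param seed Integer seed; the universe is deterministic given it.
#' @param pathway_size Length-2 integer bounds on pathway sizes
#'   (clamped to `n_genes`).
#' @param compartment_size Length-2 integer bounds on compartment sizes
#'   (clamped to `n_genes`).
#' @param n_reactions Number of reaction edges in the metabolic graph.
#' @return An object of class `annotation_universe`: list with `genes`,
#'   `proteins`, `metabolites`, `gene_sets` (named list of gene-id
#'   vectors), `compartments` (named list of gene-id vectors, overlapping),
#'   `reaction_graph` (see [read_pathway_graph()] for the schema), and the
#'   size bounds used.
#' @export
generate_universe <- function(n_genes, n_proteins, n_metabolites,
                              n_pathways, n_compartments, seed,
                              pathway_size = c(20L, 200L),
                              compartment_size = c(10L, 200L),
                              n_reactions = max(2L, n_metabolites)) {
  counts <- c(n_genes, n_proteins, n_metabolites, n_pathways, n_compartments)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all universe counts must be positive integers")
  if (n_proteins > n_genes)
    stop("n_proteins must not exceed n_genes (proteins are gene products)")
  set.seed(stream_seed(seed, "universe"))

  genes <- sprintf("g%05d", seq_len(n_genes))
  proteins <- sort(sample(genes, n_proteins))
  metabolites <- sprintf("m%04d", seq_len(n_metabolites))

  clamp <- function(b) pmin(pmax(b, 1L), n_genes)
  ps <- clamp(pathway_size); cs <- clamp(compartment_size)
  gene_sets <- lapply(seq_len(n_pathways), function(i) {
    sz <- if (ps[1] >= ps[2]) ps[1] else sample(ps[1]:ps[2], 1)
    sort(sample(genes, sz))
  })
  names(gene_sets) <- sprintf("pathway_%02d", seq_len(n_pathways))

  compartments <- lapply(seq_len(n_compartments), function(i) {
    sz <- if (cs[1] >= cs[2]) cs[1] else sample(cs[1]:cs[2], 1)
    sort(sample(genes, sz))  # membership independent per compartment: overlap allowed
  })
  names(compartments) <- sprintf("compartment_%02d", seq_len(n_compartments))

  # Reaction graph: substrate/product metabolite pairs with 1-3 evidence
  # features drawn from genes and proteins (g:/p: namespaces).
  graph <- NULL
  if (n_metabolites >= 2) {
    sub <- sample(metabolites, n_reactions, replace = TRUE)
    prod <- vapply(sub, function(s)
      sample(setdiff(metabolites, s), 1), character(1))
    ev <- vapply(seq_len(n_reactions), function(i) {
      k <- sample(1:3, 1)
      feats <- sample(genes, k)
      pre <- ifelse(feats %in% proteins & stats::runif(k) < 0.5, "p:", "g:")
      paste0(pre, feats, collapse = ";")
    }, character(1))
    graph <- data.frame(
      reaction_id = sprintf("rn%04d", seq_len(n_reactions)),
      substrate = sub, product = prod, evidence = ev,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }

  structure(
    list(
      genes = genes, proteins = proteins, metabolites = metabolites,
      gene_sets = gene_sets, compartments = compartments,
      reaction_graph = graph,
      pathway_size = ps, compartment_size = cs
    ),
    class = "annotation_universe"
  )
}

#' Plant effects into a universe
#'
#' Chooses the DE features, pathway directions, compartment enrichments and
#' batch offsets that the simulators will realize. Pathway effects are
#' planted by giving a fraction of a chosen pathway's members a common-sign
#' log2 effect (mirrored into the proteome where the gene has a protein
#' product). Compartment enrichment is planted by over-weighting
#' compartment members when sampling the background DE genes; the
#' multiplier is a relative selection weight.
#'
#' @param universe An [generate_universe()] result.
#' @param n_de_genes,n_de_metabolites Background DE counts (pathway-planted
#'   features come on top of `n_de_genes`).
#' @param effect_size Absolute log2 effect for planted features.
#' @param prop_up Fraction of background DE features planted upward.
#' @param pathways_up,pathways_down Pathway ids to plant coherently.
#' @param pathway_frac Fraction of a planted pathway's members given the
#'   effect.
#' @param compartment_weights Named multipliers (>= 1) per compartment id.
#' @param batch_offsets Named log2 shifts per proteome batch.
#' @param seed Integer seed.
#' @return A [ground_truth()] object.
#' @export
plant_truth <- function(universe, n_de_genes = 50, n_de_metabolites = 30,
                        effect_size = 2, prop_up = 0.5,
                        pathways_up = character(), pathways_down = character(),
                        pathway_frac = 0.6,
                        compartment_weights = numeric(),
                        batch_offsets = numeric(), seed = 1) {
  stopifnot(inherits(universe, "annotation_universe"))
  bad <- setdiff(c(pathways_up, pathways_down), names(universe$gene_sets))
  if (length(bad)) stop("unknown pathway id: ", paste(bad, collapse = ", "))
  if (length(compartment_weights)) {
    bad <- setdiff(names(compartment_weights), names(universe$compartments))
    if (length(bad)) stop("unknown compartment id: ", paste(bad, collapse = ", "))
    if (any(compartment_weights < 1)) stop("compartment multipliers must be >= 1")
  }
  set.seed(stream_seed(seed, "truth"))

  eff <- numeric()
  for (p in pathways_up) {
    mem <- universe$gene_sets[[p]]
    pick <- sample(mem, max(1, round(pathway_frac * length(mem))))
    eff[pick] <- effect_size
  }
  for (p in pathways_down) {
    mem <- universe$gene_sets[[p]]
    pick <- sample(mem, max(1, round(pathway_frac * length(mem))))
    eff[pick] <- -effect_size
  }

  # Background DE genes: selection weights carry the planted compartment
  # enrichment (members of an enriched compartment are w times as likely).
  pool <- setdiff(universe$genes, names(eff))
  if (n_de_genes > 0 && length(pool)) {
    w <- rep(1, length(pool))
    for (cid in names(compartment_weights)) {
      w[pool %in% universe$compartments[[cid]]] <-
        w[pool %in% universe$compartments[[cid]]] * compartment_weights[[cid]]
    }
    n_bg <- min(n_de_genes, length(pool))
    bg <- sample(pool, n_bg, prob = w)
    sgn <- ifelse(seq_len(n_bg) <= round(prop_up * n_bg), 1, -1)
    eff[bg] <- sgn[sample.int(n_bg)] * effect_size
  }

  de_proteins <- eff[names(eff) %in% universe$proteins]

  de_met <- numeric()
  if (n_de_metabolites > 0) {
    n_m <- min(n_de_metabolites, length(universe$metabolites))
    picks <- sample(universe$metabolites, n_m)
    sgn <- ifelse(seq_len(n_m) <= round(prop_up * n_m), 1, -1)
    de_met <- stats::setNames(sgn[sample.int(n_m)] * effect_size, picks)
  }

  dir <- stats::setNames(rep("null", length(universe$gene_sets)),
                         names(universe$gene_sets))
  dir[pathways_up] <- "up"
  dir[pathways_down] <- "down"

  cw <- stats::setNames(rep(1, length(universe$compartments)),
                        names(universe$compartments))
  cw[names(compartment_weights)] <- compartment_weights

  ground_truth(
    de_genes = eff, de_proteins = de_proteins, de_metabolites = de_met,
    pathway_direction = dir, enriched_compartments = cw,
    batch_offsets = batch_offsets
  )
}

#' Simulate a two-group RNA-seq count matrix
#'
#' Negative-binomial counts with per-gene log-normal baseline means, per-
#' sample library-size factors, and planted group effects: a gene with
#' planted log2 effect e has its treated-group mean scaled by `2^e`.
#'
#' @param truth A [ground_truth()] object.
#' @param universe The matching [generate_universe()] result.
#' @param n_per_group Samples per group (>= 2).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param base_mean Median baseline expression (counts).
#' @param seed Master seed; the transcriptome stream is derived from it.
#' @return An [omics_matrix()] of kind `"transcriptome"`.
#' @export
simulate_transcriptome <- function(truth, universe, n_per_group = 5,
                                   nb_dispersion = 0.1, base_mean = 200,
                                   seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(universe, "annotation_universe"))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (base_mean <= 0) stop("base_mean must be positive")
  missing_feats <- setdiff(names(truth$de_genes), universe$genes)
  if (length(missing_feats))
    stop("planted DE gene not in universe: ", missing_feats[1])
  set.seed(stream_seed(seed, "transcriptome"))

  genes <- universe$genes
  n <- 2L * n_per_group
  mu0 <- base_mean * 2^stats::rnorm(length(genes), 0, 1.5)
  eff <- stats::setNames(rep(0, length(genes)), genes)
  eff[names(truth$de_genes)] <- truth$de_genes
  libsize <- stats::runif(n, 0.7, 1.3)

  group <- rep(c("control", "treated"), each = n_per_group)
  mu <- outer(mu0, libsize) * 2^outer(eff, as.numeric(group == "treated"))
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
    nrow = length(genes),
    dimnames = list(genes, sprintf("rna_%s_%d", group,
                                   c(seq_len(n_per_group), seq_len(n_per_group))))
  )
  omics_matrix(counts, "transcriptome", group)
}

#' Simulate a batch-structured proteome intensity matrix
#'
#' Log2-normal spectrum-like intensities for the protein universe, with
#' planted group effects and additive per-batch log2 offsets taken from the
#' ground truth, emulating a TMT-plex design.
#'
#' @param truth,universe As in [simulate_transcriptome()].
#' @param n_per_group Samples per group (>= 2).
#' @param batches Character vector of batch labels, one per sample
#'   (control samples first); default alternates two batches across groups
#'   so batch is never confounded with group.
#' @param base_mean Median baseline intensity.
#' @param sd_log2 Residual log2-scale standard deviation.
#' @param seed Master seed.
#' @return An [omics_matrix()] of kind `"proteome"` with batch labels.
#' @export
simulate_proteome <- function(truth, universe, n_per_group = 4,
                              batches = NULL, base_mean = 50,
                              sd_log2 = 0.5, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(universe, "annotation_universe"))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  n <- 2L * n_per_group
  if (is.null(batches))
    batches <- rep(rep(c("b1", "b2"), length.out = n_per_group), 2)
  if (length(batches) != n || anyNA(batches) || any(!nzchar(batches)))
    stop("every sample needs a batch label")
  missing_feats <- setdiff(names(truth$de_proteins), universe$proteins)
  if (length(missing_feats))
    stop("planted DE protein not in universe: ", missing_feats[1])
  set.seed(stream_seed(seed, "proteome"))

  prots <- universe$proteins
  group <- rep(c("control", "treated"), each = n_per_group)
  mu_log2 <- log2(base_mean) + stats::rnorm(length(prots), 0, 1)
  eff <- stats::setNames(rep(0, length(prots)), prots)
  eff[names(truth$de_proteins)] <- truth$de_proteins
  boff <- rep(0, n)
  if (length(truth$batch_offsets)) {
    known <- batches %in% names(truth$batch_offsets)
    boff[known] <- truth$batch_offsets[batches[known]]
  }

  x <- outer(mu_log2, rep(0, n), `+`) +
    outer(eff, as.numeric(group == "treated")) +
    matrix(rep(boff, each = length(prots)), nrow = length(prots)) +
    matrix(stats::rnorm(length(prots) * n, 0, sd_log2), nrow = length(prots))
  vals <- 2^x
  dimnames(vals) <- list(prots, sprintf("prot_%s_%d", group,
                                        c(seq_len(n_per_group), seq_len(n_per_group))))
  omics_matrix(vals, "proteome", group, batch = batches)
}

#' Simulate a metabolome with below-detection-limit missingness
#'
#' Log-normal abundances with planted group effects and left-censoring:
#' each compound has a detection threshold placed at the
#' `missing_rate_target` quantile of its baseline (control) log-abundance
#' distribution, so realized missingness matches the target when effects
#' are sparse, and planted down-effects push extra treated-group values
#' below the limit (missing-not-at-random).
#'
#' @param truth,universe As in [simulate_transcriptome()].
#' @param n_per_group Samples per group (>= 2).
#' @param missing_rate_target Target overall missing fraction in `[0, 1)`.
#' @param base_mean Median baseline abundance.
#' @param sd_log2 Log2-scale standard deviation.
#' @param seed Master seed.
#' @return An [omics_matrix()] of kind `"metabolome"`; censored entries
#'   are `NA` with `mask` set.
#' @export
simulate_metabolome <- function(truth, universe, n_per_group = 5,
                                missing_rate_target = 0.15, base_mean = 1e5,
                                sd_log2 = 0.5, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(universe, "annotation_universe"))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (missing_rate_target < 0 || missing_rate_target >= 1)
    stop("missing_rate_target must be in [0, 1)")
  missing_feats <- setdiff(names(truth$de_metabolites), universe$metabolites)
  if (length(missing_feats))
    stop("planted DE metabolite not in universe: ", missing_feats[1])
  set.seed(stream_seed(seed, "metabolome"))

  mets <- universe$metabolites
  n <- 2L * n_per_group
  group <- rep(c("control", "treated"), each = n_per_group)
  mu_log2 <- log2(base_mean) + stats::rnorm(length(mets), 0, 1)
  eff <- stats::setNames(rep(0, length(mets)), mets)
  eff[names(truth$de_metabolites)] <- truth$de_metabolites

  x <- outer(mu_log2, rep(0, n), `+`) +
    outer(eff, as.numeric(group == "treated")) +
    matrix(stats::rnorm(length(mets) * n, 0, sd_log2), nrow = length(mets))
  vals <- 2^x
  if (missing_rate_target > 0) {
    # per-compound detection limit on the baseline distribution
    thr <- 2^(mu_log2 + sd_log2 * stats::qnorm(missing_rate_target))
    vals[vals < thr] <- NA_real_
  }
  dimnames(vals) <- list(mets, sprintf("met_%s_%d", group,
                                       c(seq_len(n_per_group), seq_len(n_per_group))))
  omics_matrix(vals, "metabolome", group)
}
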