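#' Rank features by the signed -log10(p) metric
#'
#' Builds the preranked list for gene-set enrichment: each tested feature
#' scores `sign(logFC) * (-log10 p)`, sorted descending. Ties are broken
#' by |logFC| descending and then feature id, so the order is
#' deterministic. Exact-fit features (flagged upstream) are excluded; a
#' p-value of exactly 0 reaching this stage is an error.
#'
#' @param de A `de_table` from [de_test()].
#' @return A `ranked_list` data frame with columns `feature_id`, `score`.
#' @export
rank_metric <- function(de) {
  keep <- !de$exact_fit & !is.na(de$p)
  de <- de[keep, , drop = FALSE]
  if (any(de$p == 0)) stop("invalid input: p = 0 cannot be ranked")
  score <- sign(de$logFC) * (-log10(de$p))
  ord <- order(-score, -abs(de$logFC), de$feature_id, method = "radix")
  out <- data.frame(feature_id = de$feature_id[ord], score = score[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list once: positions in the set increment the running
#' sum by `|score|^weight / sum(|score in set|^weight)`, positions outside
#' decrement by `1 / (N - n_set)`. The enrichment score is the signed
#' maximum deviation from zero. With `weight = 0` this is the classical
#' (unweighted) Kolmogorov-Smirnov statistic and the running sum ends at 0.
#'
#' @param ranked A `ranked_list` (or data frame with `feature_id`,
#'   `score`).
#' @param set Character vector of member feature ids.
#' @param weight Weight exponent on |score| for hits (default 1).
#' @return List with `es`, `running` (length-N profile) and `peak_index`.
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  n <- nrow(ranked)
  hit <- ranked$feature_id %in% set
  k <- sum(hit)
  if (k == 0L || k == n)
    stop("undefined ES: set must be a non-empty proper subset of the ranked list")
  w <- abs(ranked$score)^weight
  if (sum(w[hit]) == 0) w <- rep(1, n)  # all-zero hit scores: fall back to KS
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - k)
  running <- cumsum(inc)
  peak_index <- which.max(abs(running))
  list(es = running[peak_index], running = running, peak_index = peak_index)
}

# ES evaluated only at hit positions: O(k) once the hit positions are
# known. Equals the full running-sum maximum because the profile is
# piecewise linear between hits (checked against enrichment_score in the
# tests). `wcum` = cumulative |score|^weight at the hit positions.
es_from_positions <- function(pos, wcum, n) {
  k <- length(pos)
  nr <- wcum[k]
  p_hit <- if (nr > 0) wcum / nr else seq_len(k) / k
  dec <- 1 / (n - k)
  top <- p_hit - (pos - seq_len(k)) * dec             # just after each hit
  bot <- c(0, p_hit[-k]) - (pos - seq_len(k)) * dec   # just before each hit
  hi <- max(top)
  lo <- min(bot, (n - k) * -dec + p_hit[k])           # profile end value bound
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment with a random-set permutation null
#'
#' For each set (filtered to an effective size within `[min_size,
#' max_size]` after intersection with the ranked list), computes the
#' weighted running-sum enrichment score, then a null distribution of ES
#' from `n_perm` random feature sets of the same size drawn from the
#' ranked list. Normalization and inference follow the sign-stratified
#' convention: `NES = ES / mean(|null ES| of matching sign)`, the
#' permutation p-value is one-sided within the sign of the observed ES
#' with an add-one correction (never exactly 0), and FDR is the
#' sign-stratified ratio of null to observed NES tail fractions, with an
#' add-one correction on the null tail (so it is never exactly 0) and
#' capped at 1.
#'
#' @param ranked A `ranked_list` from [rank_metric()].
#' @param sets Named list of feature-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of random-set permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param weight Weight exponent (default 1).
#' @param min_size,max_size Effective set-size filter (defaults 5, 500).
#' @param fdr_cut Significance threshold recorded in `significant`
#'   (default 0.1).
#' @return An `enrichment_result` data frame: `set_id`, `size`, `es`,
#'   `nes`, `p_perm`, `fdr`, `direction`, `significant`, `inconclusive`.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, seed = 1, weight = 1,
                           min_size = 5, max_size = 500, fdr_cut = 0.1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight
  pos_of <- lapply(sets, function(s) which(ranked$feature_id %in% s))
  sizes <- lengths(pos_of)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep))
    return(empty_enrichment_result())
  pos_of <- pos_of[keep]
  sizes <- sizes[keep]

  set.seed(stream_seed(seed, "gsea"))
  # one shared null ES sample per distinct effective size
  null_by_size <- lapply(sort(unique(sizes)), function(k) {
    vapply(seq_len(n_perm), function(b) {
      pos <- sort.int(sample.int(n, k))
      es_from_positions(pos, cumsum(w[pos]), n)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))

  res <- lapply(seq_along(pos_of), function(i) {
    pos <- sort.int(pos_of[[i]])
    es <- es_from_positions(pos, cumsum(w[pos]), n)
    null <- null_by_size[[as.character(sizes[i])]]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    if (!length(same))
      return(data.frame(set_id = names(pos_of)[i], size = sizes[i], es = es,
                        nes = NA_real_, p_perm = NA_real_, fdr = NA_real_,
                        direction = if (es >= 0) "up" else "down",
                        significant = FALSE, inconclusive = TRUE,
                        stringsAsFactors = FALSE))
    scale <- mean(abs(same))
    nes <- es / scale
    exceed <- if (es >= 0) sum(same >= es) else sum(same <= es)
    p <- (1 + exceed) / (1 + length(same))
    data.frame(set_id = names(pos_of)[i], size = sizes[i], es = es, nes = nes,
               p_perm = p, fdr = NA_real_,
               direction = if (es >= 0) "up" else "down",
               significant = FALSE, inconclusive = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  # sign-stratified null NES pool for the ratio FDR
  null_nes <- unlist(lapply(seq_along(pos_of), function(i) {
    null <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    ifelse(null >= 0,
           if (is.nan(pos_mean)) NA_real_ else null / pos_mean,
           if (is.nan(neg_mean)) NA_real_ else null / neg_mean)
  }))
  null_nes <- null_nes[is.finite(null_nes)]
  obs_nes <- res$nes
  res$fdr <- vapply(seq_len(nrow(res)), function(i) {
    nes <- obs_nes[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num_pool <- null_nes[null_nes >= 0]; obs_pool <- obs_nes[!is.na(obs_nes) & obs_nes >= 0]
      num <- (1 + sum(num_pool >= nes)) / (1 + length(num_pool))
      den <- mean(obs_pool >= nes)
    } else {
      num_pool <- null_nes[null_nes < 0]; obs_pool <- obs_nes[!is.na(obs_nes) & obs_nes < 0]
      num <- (1 + sum(num_pool <= nes)) / (1 + length(num_pool))
      den <- mean(obs_pool <= nes)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  res$significant <- !res$inconclusive & res$fdr < fdr_cut
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

empty_enrichment_result <- function() {
  out <- data.frame(set_id = character(), size = integer(), es = numeric(),
                    nes = numeric(), p_perm = numeric(), fdr = numeric(),
                    direction = character(), significant = logical(),
                    inconclusive = logical(), stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cross-omics enrichment consensus
#'
#' Intersects two per-omic enrichment results computed over a shared set
#' collection: a set enters the consensus iff it is significant
#' (`fdr < fdr_cut`) in BOTH omics with the SAME direction. Each consensus
#' record carries the average of the two `-log10(fdr)` values and records
#' are sorted by that average, descending. Venn-style counts of
#' omic-exclusive and shared significant sets (split by direction) are
#' returned alongside. The operation is symmetric in its two inputs up to
#' column naming.
#'
#' @param res_a,res_b Two `enrichment_result` data frames (conventionally
#'   transcriptome and proteome).
#' @param fdr_cut Significance threshold (default 0.1).
#' @param labels Length-2 names used in the output (default
#'   `c("transcriptome", "proteome")`).
#' @return List with `consensus` (data frame `set_id`, `direction`,
#'   `avg_score`, `fdr_a`, `fdr_b`, `omics`) and `venn` (named counts:
#'   `a_only_up`, `a_only_down`, `b_only_up`, `b_only_down`, `shared`,
#'   plus `shared_conflict` for direction-discordant pairs).
#' @export
cross_omics_consensus <- function(res_a, res_b, fdr_cut = 0.1,
                                  labels = c("transcriptome", "proteome")) {
  shared_ids <- intersect(res_a$set_id, res_b$set_id)
  if (!length(shared_ids))
    stop("invalid input: the two results share no gene sets")
  sig <- function(r) r[!is.na(r$fdr) & r$fdr < fdr_cut & !r$inconclusive, ]
  sa <- sig(res_a); sb <- sig(res_b)
  both <- merge(sa[, c("set_id", "direction", "fdr")],
                sb[, c("set_id", "direction", "fdr")],
                by = "set_id", suffixes = c("_a", "_b"))
  agree <- both[both$direction_a == both$direction_b, , drop = FALSE]
  consensus <- data.frame(
    set_id = agree$set_id,
    direction = agree$direction_a,
    avg_score = (-log10(agree$fdr_a) - log10(agree$fdr_b)) / 2,
    fdr_a = agree$fdr_a, fdr_b = agree$fdr_b,
    omics = rep(paste(labels, collapse = ";"), nrow(agree)),
    stringsAsFactors = FALSE
  )
  consensus <- consensus[order(-consensus$avg_score, consensus$set_id), ]
  rownames(consensus) <- NULL
  venn <- c(
    a_only_up = sum(sa$direction == "up" & !(sa$set_id %in% sb$set_id)),
    a_only_down = sum(sa$direction == "down" & !(sa$set_id %in% sb$set_id)),
    b_only_up = sum(sb$direction == "up" & !(sb$set_id %in% sa$set_id)),
    b_only_down = sum(sb$direction == "down" & !(sb$set_id %in% sa$set_id)),
    shared = nrow(agree),
    shared_conflict = nrow(both) - nrow(agree)
  )
  list(consensus = consensus, venn = venn)
}
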