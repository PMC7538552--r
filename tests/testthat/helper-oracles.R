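# Independent brute-force oracles used across the test files. These stay
# deliberately naive (loops, enumeration) and share no code with the
# implementation paths they check.

# BH step-up by direct enumeration of the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) min(1, m * p[ord[j]] / j), numeric(1))
    q_sorted[i] <- min(cands)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Weighted running-sum ES by an explicit element-by-element walk.
es_bruteforce <- function(scores, is_hit, weight = 1) {
  n <- length(scores)
  k <- sum(is_hit)
  nr <- sum(abs(scores[is_hit])^weight)
  run <- 0
  best <- 0
  profile <- numeric(n)
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + if (nr > 0) abs(scores[i])^weight / nr else 1 / k
    } else {
      run <- run - 1 / (n - k)
    }
    profile[i] <- run
    if (abs(run) > abs(best)) best <- run
  }
  list(es = best, profile = profile)
}

# Hypergeometric upper tail by exhaustive enumeration of all draws
# (tiny instances only).
hyper_tail_enumerate <- function(n_universe, n_compartment, n_de, n_overlap) {
  universe <- seq_len(n_universe)
  members <- seq_len(n_compartment)
  draws <- utils::combn(universe, n_de)
  hits <- apply(draws, 2, function(d) sum(d %in% members))
  mean(hits >= n_overlap)
}

# OLS by explicit normal equations.
ols_bruteforce <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(beta = drop(beta), rss = sum(resid^2))
}

# Small fixture: a universe plus a fully null truth.
tiny_universe <- function(seed = 1, n_genes = 100, n_proteins = 50,
                          n_metabolites = 30, n_pathways = 5,
                          n_compartments = 4) {
  generate_universe(n_genes, n_proteins, n_metabolites, n_pathways,
                    n_compartments, seed = seed,
                    pathway_size = c(10, 40), compartment_size = c(10, 40))
}

null_truth <- function() ground_truth()

# A hand-set DE table for threshold and ranking tests.
toy_de_table <- function() {
  de <- data.frame(
    feature_id = sprintf("f%02d", 1:8),
    logFC = c(2, -1, 0.6, -0.4, 1.5, 0.51, -2, 0.7),
    t = NA_real_,
    p = c(0.01, 0.001, 0.04, 0.002, 0.2, 0.049, 0.03, 0.6),
    exact_fit = FALSE,
    stringsAsFactors = FALSE
  )
  de$fdr <- benjamini_hochberg(de$p)
  call_de(de)
}

# Minimal enrichment_result rows for consensus tests.
fake_enrichment <- function(set_id, fdr, direction) {
  data.frame(set_id = set_id, size = 10L, es = ifelse(direction == "up", .5, -.5),
             nes = ifelse(direction == "up", 1.5, -1.5), p_perm = fdr,
             fdr = fdr, direction = direction,
             significant = fdr < 0.1, inconclusive = FALSE,
             stringsAsFactors = FALSE)
}
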