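#' Compartment overlap ratio
#'
#' The association statistic: the number of DE features annotated to a
#' compartment divided by the total number of universe features annotated
#' to it.
#'
#' @param de_set Character vector of DE feature ids.
#' @param compartment Character vector of the compartment's member ids.
#' @return The ratio in `[0, 1]`.
#' @export
overlap_ratio <- function(de_set, compartment) {
  if (!length(compartment)) stop("empty compartment")
  length(intersect(de_set, compartment)) / length(unique(compartment))
}

#' Exact hypergeometric tail for the compartment overlap
#'
#' The closed-form twin of the resampling null: drawing `n_de` features
#' without replacement from a universe of `n_universe`, the overlap with a
#' compartment of size `n_compartment` is hypergeometric, and the upper
#' tail `P(X >= n_overlap)` is obtained by direct summation of the exact
#' point probabilities.
#'
#' @param n_universe,n_compartment,n_de,n_overlap Consistent counts.
#' @return The upper-tail probability.
#' @export
hypergeometric_oracle <- function(n_universe, n_compartment, n_de, n_overlap) {
  if (n_compartment > n_universe || n_de > n_universe ||
      n_overlap > min(n_de, n_compartment) || any(c(n_universe, n_compartment, n_de, n_overlap) < 0))
    stop("inconsistent counts")
  if (n_overlap == 0) return(1)
  ks <- n_overlap:min(n_de, n_compartment)
  sum(stats::dhyper(ks, n_compartment, n_universe - n_compartment, n_de))
}

#' Resampling test for subcellular-compartment association
#'
#' Draws, B times, `|de_set|` features at random from the universe
#' (without replacement by default) and recomputes every compartment's
#' overlap ratio on each draw — all compartments are scored against the
#' SAME B draws. The empirical p-value per compartment is
#' `(1 + #\{null ratio >= observed\}) / (B + 1)`, so it is never exactly 0
#' and floors at `1/(B+1)`. With `replace = FALSE` the null overlap count
#' is exactly hypergeometric, which [hypergeometric_oracle()] reports
#' alongside (`p_exact`). No multiple-testing correction is applied across
#' compartments.
#'
#' @param de_set Character vector of DE feature ids (subset of
#'   `universe`).
#' @param universe Character vector of all tested feature ids.
#' @param compartments Named list of member-id vectors (multi-membership
#'   across compartments allowed; each is tested marginally).
#' @param B Number of resampling draws (>= 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param replace Draw with replacement instead (non-default,
#'   unverified against the exact oracle).
#' @return A `compartment_test` data frame: `compartment_id`,
#'   `n_compartment`, `n_overlap`, `overlap_ratio`, `p_emp`, `p_exact`,
#'   `B`, `seed`; the matrix of null ratios is attached as attribute
#'   `null_ratios` (compartments x draws).
#' @export
bootstrap_compartment_test <- function(de_set, universe, compartments,
                                       B = 1000, seed = 1, replace = FALSE) {
  if (B < 100) stop("B must be >= 100")
  universe <- unique(universe)
  de_set <- unique(de_set)
  if (length(setdiff(de_set, universe)))
    stop("de_set must be a subset of the universe")
  if (!replace && length(de_set) > length(universe))
    stop("cannot draw more features than the universe holds")
  if (!length(compartments) || is.null(names(compartments)))
    stop("compartments must be a named list")
  n_u <- length(universe)
  k <- length(de_set)
  set.seed(stream_seed(seed, "bootstrap"))

  # shared draw matrix: B columns of k universe indices each
  draws <- matrix(0L, nrow = max(k, 1L), ncol = B)
  if (k > 0)
    for (b in seq_len(B))
      draws[, b] <- sample.int(n_u, k, replace = replace)

  res <- lapply(names(compartments), function(cid) {
    mem <- unique(compartments[[cid]])
    if (!length(mem)) stop("empty compartment: ", cid)
    n_c <- length(mem)
    obs <- length(intersect(de_set, mem))
    in_c <- universe %in% mem
    null_counts <- if (k > 0) colSums(matrix(in_c[draws], nrow = k)) else rep(0L, B)
    null_ratio <- null_counts / n_c
    obs_ratio <- obs / n_c
    p_emp <- (1 + sum(null_ratio >= obs_ratio)) / (B + 1)
    p_exact <- if (!replace)
      hypergeometric_oracle(n_u, sum(in_c), k, obs) else NA_real_
    list(row = data.frame(
      compartment_id = cid, n_compartment = n_c, n_overlap = obs,
      overlap_ratio = obs_ratio, p_emp = p_emp, p_exact = p_exact,
      B = B, seed = seed, stringsAsFactors = FALSE
    ), null = null_ratio)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "null_ratios") <- do.call(rbind, lapply(res, `[[`, "null"))
  rownames(attr(out, "null_ratios")) <- out$compartment_id
  class(out) <- c("compartment_test", "data.frame")
  out
}
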