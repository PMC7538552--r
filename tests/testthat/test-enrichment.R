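test_that("the signed -log10(p) rank metric orders features as specified", {
  de <- toy_de_table()
  rl <- rank_metric(de)
  scores <- stats::setNames(sign(de$logFC) * (-log10(de$p)), de$feature_id)
  expect_equal(rl$score, unname(sort(scores, decreasing = TRUE)[rl$feature_id]))
  # spot values from the formula
  expect_equal(rl$score[rl$feature_id == "f01"], -log10(0.01))
  expect_equal(rl$score[rl$feature_id == "f02"], -(-log10(0.001)) * -1 * -1)
  # full ordering matches a hand sort (scores here are untied)
  manual <- names(sort(scores, decreasing = TRUE))
  expect_identical(rl$feature_id, manual)
  # exact fits are excluded, p = 0 is an error
  de$exact_fit[1] <- TRUE
  expect_false("f01" %in% rank_metric(de)$feature_id)
  de$exact_fit[1] <- FALSE
  de$p[2] <- 0
  expect_error(rank_metric(de), "p = 0")
})

test_that("tie-breaking by |logFC| then feature id is deterministic", {
  de <- data.frame(
    feature_id = c("b", "a", "c"),
    logFC = c(1, 2, 1), p = c(0.05, 0.05, 0.05),
    exact_fit = FALSE, stringsAsFactors = FALSE
  )
  expect_identical(rank_metric(de)$feature_id, c("a", "b", "c"))
})

test_that("enrichment score extremes and brute-force equivalence", {
  rl <- data.frame(feature_id = letters[1:10],
                   score = c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5))
  top <- enrichment_score(rl, "a")
  expect_equal(top$es, 1)
  expect_equal(top$peak_index, 1)
  bottom <- enrichment_score(rl, "j")
  expect_equal(bottom$es, -1)
  expect_error(enrichment_score(rl, character()), "undefined ES")
  expect_error(enrichment_score(rl, letters[1:10]), "undefined ES")

  # random 10-feature / 3-member instances against the explicit walk
  set.seed(21)
  for (i in 1:50) {
    scores <- sort(rnorm(10), decreasing = TRUE)
    rli <- data.frame(feature_id = letters[1:10], score = scores)
    set_i <- sample(letters[1:10], 3)
    for (w in c(0, 1, 2)) {
      got <- enrichment_score(rli, set_i, weight = w)
      want <- es_bruteforce(scores, letters[1:10] %in% set_i, weight = w)
      expect_equal(got$es, want$es)
      expect_equal(got$running, want$profile)
      expect_true(abs(got$es) <= 1)
    }
  }
})

test_that("ES fast path at hit positions equals the full running sum", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(50:300, 1)
    scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    rli <- data.frame(feature_id = sprintf("f%04d", 1:n), score = scores)
    k <- sample(3:20, 1)
    set_i <- sample(rli$feature_id, k)
    full <- enrichment_score(rli, set_i, weight = 1)$es
    pos <- sort(which(rli$feature_id %in% set_i))
    w <- abs(scores)^1
    fast <- triomics:::es_from_positions(pos, cumsum(w[pos]), n)
    expect_equal(fast, full)
  }
})

test_that("weight-0 running sum ends at zero and is rescaling-invariant", {
  set.seed(23)
  scores <- sort(rnorm(40), decreasing = TRUE)
  rl <- data.frame(feature_id = sprintf("f%02d", 1:40), score = scores)
  s <- sample(rl$feature_id, 6)
  r0 <- enrichment_score(rl, s, weight = 0)
  expect_equal(r0$running[40], 0)
  scaled <- rl
  scaled$score <- scaled$score * 13.7
  expect_equal(enrichment_score(scaled, s, weight = 0)$es, r0$es)
  # peak index invariant under positive rescaling for any weight
  for (w in c(0.5, 1, 2)) {
    expect_equal(enrichment_score(scaled, s, weight = w)$peak_index,
                 enrichment_score(rl, s, weight = w)$peak_index)
  }
})

test_that("ES agrees with an independent GSEA implementation", {
  set.seed(24)
  scores <- sort(rnorm(100, sd = 2), decreasing = TRUE)
  rl <- data.frame(feature_id = sprintf("f%03d", 1:100), score = scores)
  for (k in c(5, 15)) {
    s <- sample(rl$feature_id, k)
    ours <- enrichment_score(rl, s, weight = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(scores, rl$feature_id),
                               selectedStats = which(rl$feature_id %in% s),
                               gseaParam = 1, scoreType = "std")
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("permutation p floors above zero and extreme sets hit the floor", {
  set.seed(25)
  scores <- sort(c(rnorm(10, 6, 0.5), rnorm(190)), decreasing = TRUE)
  rl <- data.frame(feature_id = sprintf("f%03d", 1:200), score = scores)
  sets <- list(top = rl$feature_id[1:10])
  res <- preranked_gsea(rl, sets, n_perm = 400, seed = 1)
  expect_gt(res$p_perm, 0)
  expect_lte(res$p_perm, 2.5 / 401)
  expect_equal(res$direction, "up")
  expect_true(res$significant)
})

test_that("random sets give approximately uniform permutation p-values", {
  set.seed(26)
  scores <- sort(rnorm(300), decreasing = TRUE)
  rl <- data.frame(feature_id = sprintf("f%03d", 1:300), score = scores)
  sets <- lapply(1:200, function(i) sample(rl$feature_id, 15))
  names(sets) <- sprintf("rand_%03d", 1:200)
  res <- preranked_gsea(rl, sets, n_perm = 200, seed = 2)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("set-size filtering and NES sign conventions hold", {
  set.seed(27)
  scores <- sort(rnorm(100), decreasing = TRUE)
  rl <- data.frame(feature_id = sprintf("f%03d", 1:100), score = scores)
  sets <- list(tiny = rl$feature_id[1:3],
               ok = sample(rl$feature_id, 10),
               huge = rl$feature_id[1:80])
  res <- preranked_gsea(rl, sets, n_perm = 200, seed = 3,
                        min_size = 5, max_size = 50)
  expect_identical(res$set_id, "ok")
  expect_equal(sign(res$nes), sign(res$es))
})

test_that("cross-omics consensus applies the same-direction rule and Venn counts", {
  res_t <- fake_enrichment(c("p1", "p2", "p3", "p4", "p5", "p6"),
                           c(0.01, 0.05, 0.02, 0.5, 0.03, 0.04),
                           c("up", "up", "down", "up", "up", "down"))
  res_p <- fake_enrichment(c("p1", "p2", "p3", "p4", "p5", "p6"),
                           c(0.001, 0.2, 0.01, 0.02, 0.04, 0.03),
                           c("up", "up", "down", "up", "down", "up"))
  out <- cross_omics_consensus(res_t, res_p)
  # p1 up/up, p3 down/down enter; p5 and p6 conflict; p2, p4 single-omic
  expect_setequal(out$consensus$set_id, c("p1", "p3"))
  expect_equal(out$consensus$avg_score[out$consensus$set_id == "p1"],
               (2 + 3) / 2)
  expect_identical(out$consensus$set_id[1], "p1")  # sorted by avg_score
  expect_equal(unname(out$venn["shared"]), 2)
  expect_equal(unname(out$venn["shared_conflict"]), 2)
  expect_equal(unname(out$venn["a_only_up"]), 1)   # p2
  expect_equal(unname(out$venn["b_only_up"]), 1)   # p4
  # symmetric in its inputs
  swapped <- cross_omics_consensus(res_p, res_t)
  expect_setequal(swapped$consensus$set_id, out$consensus$set_id)
  expect_equal(swapped$consensus$avg_score, out$consensus$avg_score)
  expect_error(cross_omics_consensus(res_t, fake_enrichment("zz", 0.01, "up")),
               "share no gene sets")
})
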