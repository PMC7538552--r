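# independent statement of the color rule used in the exhaustive check
expected_state <- function(dirs) {
  if (!length(dirs)) "unpainted"
  else if (all(dirs == "up")) "up_red"
  else if (all(dirs == "down")) "down_blue"
  else "conflict_purple"
}

test_that("edge painting matches the red/blue/purple semantics exhaustively", {
  # every evidence configuration of up to two gene votes and two protein
  # votes, each vote in {absent (non-DE), up, down}
  vote_states <- c("none", "up", "down")
  grid <- expand.grid(g1 = vote_states, g2 = vote_states,
                      p1 = vote_states, p2 = vote_states,
                      stringsAsFactors = FALSE)
  graph <- data.frame(reaction_id = sprintf("r%03d", seq_len(nrow(grid))),
                      substrate = "mA", product = "mB",
                      evidence = "g:ga;g:gb;p:pa;p:pb",
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    de_g <- stats::setNames(c(row$g1, row$g2), c("ga", "gb"))
    de_g <- de_g[de_g != "none"]
    de_p <- stats::setNames(c(row$p1, row$p2), c("pa", "pb"))
    de_p <- de_p[de_p != "none"]
    got <- paint_edges(graph[i, ], de_g, de_p)$state
    expect_identical(got, expected_state(c(de_g, de_p)))
  }
})

test_that("canonical evidence combinations give the stated colors", {
  graph <- data.frame(reaction_id = c("r1", "r2", "r3"),
                      substrate = "mA", product = "mB",
                      evidence = c("g:g1;p:p1", "g:g1;p:p2", "g:g9"),
                      stringsAsFactors = FALSE)
  de_g <- c(g1 = "up")
  de_p <- c(p1 = "up", p2 = "down")
  st <- paint_edges(graph, de_g, de_p)$state
  expect_identical(st, c("up_red", "conflict_purple", "unpainted"))
  # magnitude is never consulted: removing a non-DE evidence feature from
  # an edge does not change its state
  graph2 <- graph
  graph2$evidence[3] <- "g:g9;p:p9"
  expect_identical(paint_edges(graph2, de_g, de_p)$state[3], "unpainted")
})

test_that("evidence validation catches unknown features and bad prefixes", {
  graph <- data.frame(reaction_id = "r1", substrate = "mA", product = "mB",
                      evidence = "g:g1", stringsAsFactors = FALSE)
  expect_error(paint_edges(graph, c(g1 = "sideways"), character()), "up")
  expect_error(paint_edges(graph, c(g1 = "up"), character(),
                           gene_universe = "other"), "invalid graph")
  bad <- graph; bad$evidence <- "x:g1"
  expect_error(paint_edges(bad, c(g1 = "up"), character()), "g:/p:")
})

test_that("node painting applies the capped gradient only to DE metabolites", {
  graph <- data.frame(reaction_id = c("r1", "r2"),
                      substrate = c("m1", "m2"), product = c("m2", "m3"),
                      evidence = "g:g1", stringsAsFactors = FALSE)
  lfc <- c(m1 = 3, m2 = -1.5, m3 = 10)[c("m1", "m2")]  # m3 not DE
  nodes <- paint_nodes(graph, lfc, cap = 3)
  expect_identical(nodes$state[nodes$metabolite_id == "m1"], "up_red")
  expect_equal(nodes$intensity[nodes$metabolite_id == "m1"], 1)
  expect_identical(nodes$state[nodes$metabolite_id == "m2"], "down_blue")
  expect_equal(nodes$intensity[nodes$metabolite_id == "m2"], 0.5)
  expect_identical(nodes$state[nodes$metabolite_id == "m3"], "unpainted")
  expect_true(is.na(nodes$intensity[nodes$metabolite_id == "m3"]))
  # cap clamps extreme fold changes
  nodes2 <- paint_nodes(graph, c(m3 = 10), cap = 3)
  expect_equal(nodes2$intensity[nodes2$metabolite_id == "m3"], 1)
  expect_error(paint_nodes(graph, lfc, cap = 0), "cap")
})

test_that("painting is pure and summaries partition elements", {
  u <- tiny_universe(seed = 41)
  graph <- u$reaction_graph
  de_g <- stats::setNames(rep(c("up", "down"), 10), u$genes[1:20])
  de_p <- stats::setNames(rep("up", 5), u$proteins[1:5])
  e1 <- paint_edges(graph, de_g, de_p, u$genes, u$proteins)
  e2 <- paint_edges(graph, de_g, de_p, u$genes, u$proteins)
  expect_identical(e1, e2)
  n1 <- paint_nodes(graph, c(m0001 = 1))
  s <- summarize_painting(e1, n1)
  expect_equal(sum(s$edges), nrow(graph))
  expect_equal(sum(s$nodes), length(unique(c(graph$substrate, graph$product))))
  # empty DE sets leave everything unpainted
  e0 <- paint_edges(graph, character(), character())
  n0 <- paint_nodes(graph, numeric())
  s0 <- summarize_painting(e0, n0)
  expect_equal(unname(s0$edges["unpainted"]), nrow(graph))
  expect_equal(sum(s0$edges[c("up_red", "down_blue", "conflict_purple")]), 0)
  expect_equal(unname(s0$nodes["unpainted"]), sum(s0$nodes))
})

test_that("a hand-built 5-edge graph tallies as enumerated", {
  graph <- data.frame(
    reaction_id = paste0("r", 1:5),
    substrate = c("m1", "m2", "m3", "m1", "m2"),
    product = c("m2", "m3", "m1", "m3", "m1"),
    evidence = c("g:a", "g:a;g:b", "p:c", "g:z", "g:b;p:c"),
    stringsAsFactors = FALSE
  )
  de_g <- c(a = "up", b = "down")
  de_p <- c(c = "down")
  st <- paint_edges(graph, de_g, de_p)$state
  # r1: up; r2: up+down = purple; r3: down; r4: no DE; r5: down+down = blue
  expect_identical(st, c("up_red", "conflict_purple", "down_blue",
                         "unpainted", "down_blue"))
  s <- summarize_painting(paint_edges(graph, de_g, de_p),
                          paint_nodes(graph, numeric()))
  expect_equal(as.integer(s$edges[c("up_red", "down_blue", "conflict_purple",
                                    "unpainted")]), c(1L, 2L, 1L, 1L))
})
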