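# Shared fixture: diamond GO graph r <- {a, b} <- c with four genes.
# Closure gives G_c = {g2}, G_a = {g1, g2}, G_b = {g2, g3}, G_r = all 4.
diamond_graph <- function() {
  dag <- ontology_dag(c("a", "b", "c", "c"), c("r", "r", "a", "b"))
  ann <- assoc_table(c("g1", "g2", "g3", "g4"), c("a", "c", "b", "r"))
  suppressMessages(annotated_go_graph(dag, ann))
}

test_that("information content uses true-path gene sets, natural log", {
  g <- diamond_graph()
  expect_equal(g$gene_sets$a, c("g1", "g2"))
  expect_equal(g$gene_sets$r, c("g1", "g2", "g3", "g4"))
  expect_equal(information_content(g, "r"), 0)
  expect_equal(information_content(g, "a"), -log(2 / 4))
  expect_equal(information_content(g, "c"), -log(1 / 4))
  expect_error(information_content(g, "nope"), "nope")

  # zero-gene terms are pruned before IC
  dag <- ontology_dag(c("a", "b"), c("r", "r"))
  ann <- assoc_table("g1", "a")
  g2 <- suppressMessages(annotated_go_graph(dag, ann))
  expect_false("b" %in% names(g2$ic))
})

test_that("IC is monotone non-decreasing from parent to child", {
  for (seed in 1:5) {
    dag <- gen_ontology(12, max_parents = 2, seed = seed, prefix = "GO")
    ann <- gen_go_annotations(dag, sprintf("g%02d", 1:20), seed = seed)
    g <- suppressMessages(annotated_go_graph(dag, ann))
    edges <- igraph::as_data_frame(g$dag$graph, what = "edges")
    for (i in seq_len(nrow(edges))) {
      expect_gte(g$ic[[edges$from[i]]], g$ic[[edges$to[i]]])
    }
    expect_true(all(vapply(g$gene_sets, function(s) {
      all(s %in% g$gene_sets[[g$dag$roots[1]]])
    }, TRUE)))
  }
})

test_that("LCA and HCD are the extremal common ancestors/descendants", {
  g <- diamond_graph()
  expect_equal(lca_hcd(g, "a", "a"), list(L = "a", H = "a"))
  # diamond parents: lowest common ancestor is the root, highest
  # common descendant their shared child
  expect_equal(lca_hcd(g, "a", "b"), list(L = "r", H = "c"))

  # siblings with no shared child
  dag <- ontology_dag(c("a", "b"), c("r", "r"))
  ann <- assoc_table(c("g1", "g2"), c("a", "b"))
  g2 <- suppressMessages(annotated_go_graph(dag, ann))
  expect_equal(lca_hcd(g2, "a", "b"), list(L = "r", H = character(0)))
})

test_that("GO term similarity matches hand-worked cases", {
  g <- diamond_graph()
  expect_equal(go_term_similarity(g, "c", "c"), 1)
  expect_equal(go_term_similarity(g, "r", "r"), 1)  # root self-pair

  # siblings under the bare root share nothing informative
  dag <- ontology_dag(c("a", "b"), c("r", "r"))
  ann <- assoc_table(c("g1", "g2"), c("a", "b"))
  g2 <- suppressMessages(annotated_go_graph(dag, ann))
  expect_equal(go_term_similarity(g2, "a", "b"), 0)

  # IC_L / (IC_x + IC_y) with no common descendant: siblings x, y under
  # mid with G_x = G_y = 2 genes, G_mid = 4, background 16
  dag <- ontology_dag(c("m", "x", "y"), c("r", "m", "m"))
  ann <- assoc_table(c("g1", "g2", "g3", "g4", sprintf("g%d", 5:16)),
                     c("x", "x", "y", "y", rep("r", 12)))
  g3 <- suppressMessages(annotated_go_graph(dag, ann))
  expect_equal(go_term_similarity(g3, "x", "y"),
               log(4) / (2 * log(8)))  # = 1/3
  # symmetry and range over all pairs
  for (t1 in names(g3$ic)) {
    for (t2 in names(g3$ic)) {
      s <- go_term_similarity(g3, t1, t2)
      expect_identical(s, go_term_similarity(g3, t2, t1))
      expect_gte(s, 0); expect_lte(s, 1)
    }
  }
})

test_that("term weight is the -log upper-tail hypergeometric surprise", {
  expect_equal(term_weight(10, 5, 4, 0), 0)
  expect_equal(term_weight(10, 5, 4, 4), -log(5 / 210))
  expect_equal(term_weight(10, 5, 4, 1), -log(1 - 5 / 210))
  expect_error(term_weight(10, 5, 4, 5), "impossible")
  expect_error(term_weight(10, 11, 4, 2), "impossible")

  # enumeration oracle over all draws at a spread of counts
  for (N in c(6, 9, 12)) {
    for (n in c(2, N %/% 2)) {
      for (M in c(1, N %/% 2, N - 1)) {
        for (k in 0:min(n, M)) {
          expect_equal(term_weight(N, M, n, k),
                       if (k == 0) 0 else -log(enum_hyper_tail(N, M, n, k)),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("miRNA GO-profile similarity matches the decided aggregation", {
  wq <- structure(list(weights = c(x = 2)), class = "term_weighting")
  wt <- structure(list(weights = c(y = 1)), class = "term_weighting")
  ts <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("x", "y"),
                                                     c("x", "y")))
  expect_equal(mirgofs_similarity(NULL, wq, wt, term_sim = ts), 0.5)
  # identical term sets and weights -> 1 regardless of the weights
  w2 <- structure(list(weights = c(x = 2, y = 7)),
                  class = "term_weighting")
  expect_equal(mirgofs_similarity(NULL, w2, w2, term_sim = ts), 1)
  # all-zero cross similarities -> 0
  ts0 <- ts; ts0["x", "y"] <- ts0["y", "x"] <- 0
  expect_equal(mirgofs_similarity(NULL, wq, wt, term_sim = ts0), 0)
})

test_that("miRSN-GOA equals pairwise similarity and excludes unannotated", {
  dag <- gen_ontology(8, max_parents = 2, seed = 21, prefix = "GO")
  genes <- sprintf("g%02d", 1:15)
  ann <- gen_go_annotations(dag, genes, seed = 21)
  targets <- gen_associations(sprintf("mir-%d", 1:4), genes,
                              density = 0.3, seed = 21)
  net <- suppressMessages(build_mirsn_goa(targets, dag, ann))
  expect_s3_class(net, "sim_matrix")

  graph <- suppressMessages(annotated_go_graph(dag, ann))
  for (a in sim_ids(net)) {
    for (b in sim_ids(net)) {
      if (a >= b) next
      expected <- mirgofs_similarity(
        graph,
        term_weighting(graph, targets$by_mirna[[a]]),
        term_weighting(graph, targets$by_mirna[[b]]))
      expect_equal(unname(net[a, b]), expected, tolerance = 1e-12)
    }
  }

  # identical target sets give similarity 1
  t2 <- assoc_table(c("mA", "mA", "mB", "mB"), c("g01", "g02", "g01", "g02"))
  net2 <- suppressMessages(build_mirsn_goa(t2, dag, ann))
  expect_equal(unname(net2["mA", "mB"]), 1)

  # a miRNA whose targets carry no GO annotation is excluded, logged
  t3 <- assoc_table(c("mA", "mA", "mC"), c("g01", "g02", "not-a-gene"))
  msgs <- capture_messages(net3 <- build_mirsn_goa(t3, dag, ann))
  expect_true(any(grepl("excluded 1", msgs)))
  expect_false("mC" %in% sim_ids(net3))
})

test_that("GO-profile similarity ignores term order and duplicate rows", {
  dag <- gen_ontology(8, max_parents = 2, seed = 22, prefix = "GO")
  genes <- sprintf("g%02d", 1:12)
  ann <- gen_go_annotations(dag, genes, seed = 22)
  graph <- suppressMessages(annotated_go_graph(dag, ann))
  dup <- assoc_table(rep(ann$pairs$mirna, 2), rep(ann$pairs$annotation, 2))
  graph_dup <- suppressMessages(annotated_go_graph(dag, dup))
  wa <- term_weighting(graph, c("g01", "g03", "g05"))
  wb <- term_weighting(graph, c("g02", "g04"))
  wa2 <- term_weighting(graph_dup, c("g05", "g01", "g03"))
  wb2 <- term_weighting(graph_dup, c("g04", "g02"))
  expect_equal(mirgofs_similarity(graph, wa, wb),
               mirgofs_similarity(graph_dup, wa2, wb2))
})
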