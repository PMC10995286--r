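make_S <- function(ids, fill) {
  n <- length(ids)
  v <- matrix(fill, n, n, dimnames = list(ids, ids))
  v <- (v + t(v)) / 2
  diag(v) <- 1
  sim_matrix(v, ids)
}

test_that("disease-to-set similarity is the best match over the set", {
  S <- make_S(c("d", "a", "b"), 0)
  S["d", "a"] <- S["a", "d"] <- 0.2
  S["d", "b"] <- S["b", "d"] <- 0.7
  S <- sim_matrix(unclass(S), sim_ids(S))
  expect_equal(disease_to_set_similarity("d", c("d", "a"), S), 1)
  expect_equal(disease_to_set_similarity("d", c("a", "b"), S), 0.7)
  expect_error(disease_to_set_similarity("d", character(0), S), "empty")

  # brute-force max over a random 6-disease fixture
  withr::local_seed(3)
  S6 <- random_sim_matrix(6, sprintf("dis-%d", 1:6))
  D <- c("dis-2", "dis-4", "dis-5")
  expect_equal(disease_to_set_similarity("dis-1", D, S6),
               max(vapply(D, function(di) S6["dis-1", di], 1.0)))
})

test_that("misim matches hand-worked disease-set averages", {
  # identical singleton disease sets
  S <- make_S(c("d"), 0)
  assoc <- assoc_table(c("m1", "m2"), c("d", "d"))
  expect_equal(misim("m1", "m2", assoc, S), 1)

  # disjoint singletons with similarity 0.4: (0.4 + 0.4) / 2
  S <- make_S(c("a", "b"), 0.4)
  assoc <- assoc_table(c("m1", "m2"), c("a", "b"))
  expect_equal(misim("m1", "m2", assoc, S), 0.4)

  # D1 = {a, b}, D2 = {b}, S(a,b) = 1/3: (1/3 + 1 + 1) / 3
  S <- make_S(c("a", "b"), 1 / 3)
  assoc <- assoc_table(c("m1", "m1", "m2"), c("a", "b", "b"))
  expect_equal(misim("m1", "m2", assoc, S), 7 / 9)

  expect_error(misim("m1", "mx", assoc, S), "mx")
})

test_that("misim is symmetric, bounded and order-invariant", {
  withr::local_seed(9)
  S <- random_sim_matrix(6, sprintf("dis-%d", 1:6))
  assoc <- gen_associations(sprintf("mir-%d", 1:5), sim_ids(S),
                            density = 0.5, seed = 9)
  mirnas <- names(assoc$by_mirna)
  for (i in seq_along(mirnas)) {
    for (j in seq_along(mirnas)) {
      s <- misim(mirnas[[i]], mirnas[[j]], assoc, S)
      expect_identical(s, misim(mirnas[[j]], mirnas[[i]], assoc, S))
      expect_gte(s, 0); expect_lte(s, 1)
    }
  }
  # permuting the stored disease order never changes a value
  shuffled <- assoc_table(rev(assoc$pairs$mirna), rev(assoc$pairs$annotation))
  expect_equal(misim(mirnas[[1]], mirnas[[2]], shuffled, S),
               misim(mirnas[[1]], mirnas[[2]], assoc, S))
})

test_that("miRSN-DA network equals pairwise misim and applies exclusions", {
  # sharing the single disease vs disjoint zero-similarity sets
  dag <- ontology_dag(c("d1", "d2"), c("r1", "r2"))
  assoc <- assoc_table(c("m1", "m2"), c("d1", "d1"))
  m <- suppressMessages(build_mirsn_da(assoc, dag))
  expect_equal(unname(m["m1", "m2"]), 1)
  assoc <- assoc_table(c("m1", "m2"), c("d1", "d2"))
  m <- suppressMessages(build_mirsn_da(assoc, dag))
  expect_equal(unname(m["m1", "m2"]), 0)

  # 5-miRNA fixture: network equals pairwise misim on the same S
  dag <- gen_ontology(10, max_parents = 2, seed = 5, prefix = "D")
  assoc <- gen_associations(sprintf("mir-%d", 1:5), dag$terms,
                            density = 0.3, seed = 5)
  net <- suppressMessages(build_mirsn_da(assoc, dag))
  S <- disease_similarity_matrix(dag, sort(unique(assoc$pairs$annotation)))
  for (a in sim_ids(net)) {
    for (b in sim_ids(net)) {
      if (a != b) expect_equal(unname(net[a, b]), misim(a, b, assoc, S))
    }
  }

  # a miRNA whose only disease is off-ontology is excluded, logged
  assoc <- assoc_table(c("m1", "m2", "m3"), c("D001", "D002", "unknown"))
  msgs <- capture_messages(net <- build_mirsn_da(assoc, dag))
  expect_true(any(grepl("excluded 1", msgs)))
  expect_setequal(sim_ids(net), c("m1", "m2"))
  # no eligible miRNA at all is an error
  assoc <- assoc_table("m1", "unknown")
  expect_error(suppressMessages(build_mirsn_da(assoc, dag)), "no miRNA")
})
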