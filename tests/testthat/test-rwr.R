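two_node_W <- function() {
  matrix(c(0, 1, 1, 0), 2, dimnames = list(c("n1", "n2"), c("n1", "n2")))
}

test_that("thresholding keeps >= tau, zeroes the rest and the diagonal", {
  v <- matrix(c(1, 0.7, 0.5, 0.7, 1, 0.6, 0.5, 0.6, 1), 3)
  m <- sim_matrix(v, c("a", "b", "c"))
  adj <- threshold_network(m, 0.6)
  expect_equal(unname(adj["a", "b"]), 0.7)   # kept
  expect_equal(unname(adj["a", "c"]), 0)     # removed
  expect_equal(unname(adj["b", "c"]), 0.6)   # boundary: kept
  expect_equal(unname(diag(adj)), rep(0, 3))
  # tau = 0 keeps every off-diagonal edge
  adj0 <- threshold_network(m, 0)
  expect_true(all(adj0[upper.tri(adj0)] > 0))
})

test_that("transition matrix is column-stochastic where possible", {
  m <- sim_matrix(matrix(c(1, 0.8, 0.8, 1), 2), c("a", "b"))
  W <- transition_matrix(threshold_network(m, 0.6))
  expect_equal(unname(W), matrix(c(0, 1, 1, 0), 2))

  # isolated node keeps an all-zero column
  v <- diag(3); v[1, 2] <- v[2, 1] <- 0.9
  W <- transition_matrix(threshold_network(sim_matrix(v, c("a", "b", "c")),
                                           0.6))
  expect_equal(unname(W[, "c"]), rep(0, 3))

  sc <- gen_planted_scenario(n_mirnas = 20, module_size = 8, seed = 3)
  W <- transition_matrix(threshold_network(sc$networks$da, 0.6))
  sums <- colSums(W)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
})

test_that("random walk matches closed forms and the linear-solve oracle", {
  # two nodes, one edge, seed n1, c = 0.5: r = (2/3, 1/3)
  r <- rwr(two_node_W(), "n1", c = 0.5)
  expect_equal(as.vector(r), c(2, 1) / 3, tolerance = 1e-9)

  # c -> 0 limit: r == e
  r <- rwr(two_node_W(), "n1", c = 1e-12)
  expect_equal(as.vector(r), c(1, 0), tolerance = 1e-9)

  # linear-system oracle on random thresholded networks up to 12 nodes
  for (seed in 1:10) {
    sc <- gen_planted_scenario(n_mirnas = 12, module_size = 5, seed = seed)
    W <- transition_matrix(threshold_network(sc$networks$da, 0.6))
    seeds <- sc$input_list
    r <- rwr(W, seeds, c = 0.85)
    e <- stats::setNames(numeric(nrow(W)), rownames(W))
    e[intersect(seeds, rownames(W))] <-
      1 / length(intersect(seeds, rownames(W)))
    expect_equal(as.vector(r), solve_rwr(W, e, 0.85), tolerance = 1e-8)
  }

  expect_error(rwr(two_node_W(), "nope", c = 0.5), "no seed")
  expect_error(rwr(two_node_W(), "n1", c = 0.99, max_iter = 2L),
               "did not converge")
})

test_that("walk scores conserve probability and residuals contract", {
  sc <- gen_planted_scenario(n_mirnas = 30, module_size = 12, seed = 5)
  fused <- fuse_networks(sc$networks[c("da", "goa")])
  W <- transition_matrix(threshold_network(fused, 0.6))
  # module nodes all link within the module, so no dangling seed mass
  r <- rwr(W, sc$input_list, c = 0.85)
  dangling <- colnames(W)[colSums(W) == 0]
  if (!length(intersect(dangling, sc$input_list))) {
    expect_equal(sum(r[colSums(W) > 0]) + sum(r[dangling]), 1,
                 tolerance = 1e-9)
  }
  # manual iteration: residual sequence is monotone non-increasing
  e <- stats::setNames(numeric(nrow(W)), rownames(W))
  e[intersect(sc$input_list, rownames(W))] <-
    1 / length(intersect(sc$input_list, rownames(W)))
  res <- numeric(0)
  x <- e
  for (i in 1:40) {
    x_new <- 0.85 * as.vector(W %*% x) + 0.15 * e
    res <- c(res, sum(abs(x_new - x)))
    x <- x_new
  }
  expect_true(all(diff(res) <= 1e-15))
})

test_that("list expansion ranks, cuts at the floor and keeps absentees", {
  scores <- c(m1 = 0.4, m2 = 0.3, m3 = 0.2, m4 = 0.1, m5 = 0.05, m6 = 0)
  seeds <- c("m1", "m2")
  # 3 positive non-seed candidates, fraction 0.5 -> floor(1.5) = 1 kept
  res <- expand_list(scores, seeds, seeds, keep_fraction = 0.5)
  expect_equal(res$added, "m3")
  expect_setequal(res$expanded_list, c("m1", "m2", "m3"))

  # 4 candidates at fraction 0.5 -> exactly 2
  scores2 <- c(scores, m7 = 0.02)
  res <- expand_list(scores2, seeds, seeds, keep_fraction = 0.5)
  expect_equal(res$added, c("m3", "m4"))

  # tie at the cut broken lexicographically: mir-a wins over mir-b
  scores3 <- c(s1 = 1, `mir-b` = 0.5, `mir-a` = 0.5, other = 0.4)
  res <- expand_list(scores3, "s1", "s1", keep_fraction = 1 / 3)
  expect_equal(res$added, "mir-a")

  # all non-seed scores zero: expansion returns the input unchanged
  res <- expand_list(c(m1 = 1, m2 = 0), "m1", c("m1", "mx"),
                     keep_fraction = 0.5)
  expect_equal(res$expanded_list, c("m1", "mx"))
  expect_equal(res$added, character(0))

  # input miRNAs absent from the network are carried through
  sc <- gen_planted_scenario(n_mirnas = 20, module_size = 8, seed = 2)
  res <- expand_mirna_list(sc$networks$da,
                           c(sc$input_list, "mir-absent"))
  expect_true("mir-absent" %in% res$expanded_list)

  # determinism: identical inputs, identical output
  r1 <- expand_mirna_list(sc$networks$da, sc$input_list)
  r2 <- expand_mirna_list(sc$networks$da, sc$input_list)
  expect_identical(r1$expanded_list, r2$expanded_list)
})
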