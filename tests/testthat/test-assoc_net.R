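tri_a <- pathway_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")), name = "a")
tri_b <- pathway_network(rbind(c("B", "C"), c("C", "D"), c("B", "D")), name = "b")

test_that("two triangles sharing an edge produce the hand-counted association", {
  assoc <- build_association(tri_a, tri_b)
  cnt <- count_components(assoc)
  expect_equal(unclass(cnt)[c("n_a", "n_b", "n_ab", "e_ab", "n_r", "e_r", "e_d")],
               list(n_a = 3L, n_b = 3L, n_ab = 4L, e_ab = 5L, n_r = 2L,
                    e_r = 1L, e_d = 0L))
  sc <- association_coefficient(cnt)
  expect_equal(sc$c_n, 0.5)
  expect_equal(sc$c_e, 0.2)
  expect_equal(sc$c, sqrt(0.145))
  expect_false(sc$edgeless)
})

test_that("interactome edges between union nodes become derived edges", {
  inter <- interactome(rbind(c("A", "D"), c("X", "Y"), c("A", "B")))
  assoc <- build_association(tri_a, tri_b, inter)
  expect_equal(nrow(assoc$edges), 6L)
  derived <- assoc$edges[assoc$edges$label == "derived", ]
  expect_equal(nrow(derived), 1L)      # X-Y outside the union; A-B already in a
  expect_equal(edge_key(derived$from, derived$to), "A|D")
  expect_false("X" %in% assoc$nodes$node)  # interactome never adds nodes
})

test_that("cross-only mode drops derived edges within a single pathway side", {
  a <- pathway_network(rbind(c("A1", "A2")), nodes = c("A3"), name = "a")
  b <- pathway_network(rbind(c("B1", "B2")), name = "b")
  inter <- interactome(rbind(c("A1", "A3"), c("A1", "B1")))
  any_mode <- build_association(a, b, inter, derived = "any")
  cross <- build_association(a, b, inter, derived = "cross-only")
  expect_equal(sum(any_mode$edges$label == "derived"), 2L)
  d <- cross$edges[cross$edges$label == "derived", ]
  expect_equal(edge_key(d$from, d$to), "A1|B1")
})

test_that("a network associated with itself scores exactly 1", {
  assoc <- build_association(tri_a, tri_a)
  expect_true(all(assoc$nodes$label == "shared"))
  expect_true(all(assoc$edges$label == "overlapping"))
  expect_equal(association_coefficient(count_components(assoc))$c, 1)
})

test_that("edgeless associated networks fall back to the node coefficient", {
  a <- pathway_network(nodes = c("A", "B"), name = "a")
  b <- pathway_network(nodes = c("B", "C"), name = "b")
  sc <- association_coefficient(count_components(build_association(a, b)))
  expect_true(sc$edgeless)
  expect_equal(sc$c, 1 / 3)
  expect_true(is.na(sc$c_e))
})

test_that("empty associated network is an error", {
  a <- pathway_network(name = "a")
  expect_error(association_coefficient(count_components(build_association(a, a))),
               "N_ab = 0")
})

test_that("counts match the brute-force set-intersection oracle on random pairs", {
  for (seed in 1:25) {
    fx <- synth_pathway_pair(10 + seed %% 6, 8 + seed %% 8, seed %% 5,
                             0.1 + 0.07 * (seed %% 6), n_derived = seed %% 4,
                             seed = seed)
    assoc <- build_association(fx$net_a, fx$net_b, fx$interactome)
    cnt <- count_components(assoc)
    orc <- oracle_counts(fx$net_a, fx$net_b, fx$interactome)
    expect_equal(cnt$n_ab, orc$n_ab)
    expect_equal(cnt$e_ab, orc$e_ab)
    expect_equal(cnt$n_r, orc$n_r)
    expect_equal(cnt$e_r, orc$e_r)
    expect_equal(cnt$e_d, orc$e_d)
  }
})

test_that("association is symmetric and bounded on random pairs", {
  for (seed in 1:20) {
    fx <- synth_pathway_pair(9, 11, seed %% 6, 0.3, n_derived = seed %% 3,
                             seed = 100 + seed)
    ab <- association_coefficient(count_components(
      build_association(fx$net_a, fx$net_b, fx$interactome)))
    ba <- association_coefficient(count_components(
      build_association(fx$net_b, fx$net_a, fx$interactome)))
    expect_equal(ab$c, ba$c)
    expect_true(ab$c >= 0 && ab$c <= 1)
    expect_true(ab$c_n >= 0 && ab$c_n <= 1)
  }
})

test_that("adding a derived edge never decreases the edge coefficient", {
  for (seed in 1:10) {
    fx <- synth_pathway_pair(8, 8, 3, 0.35, n_derived = 3, seed = 200 + seed)
    ce <- function(f) association_coefficient(count_components(
      build_association(f$net_a, f$net_b, f$interactome)))$c_e
    cnt <- oracle_counts(fx$net_a, fx$net_b, fx$interactome)
    c1 <- oracle_coefficient(cnt)
    cnt2 <- cnt; cnt2$e_d <- cnt$e_d + 1L; cnt2$e_ab <- cnt$e_ab + 1L
    c2 <- oracle_coefficient(cnt2)
    expect_gte(c2$c_e, c1$c_e)
    expect_equal(ce(fx),
                 oracle_coefficient(oracle_counts(fx$net_a, fx$net_b,
                                                  fx$interactome))$c_e)
  }
})

test_that("weighted association with the worked node weights matches hand values", {
  assoc <- build_association(tri_a, tri_b)
  node_w <- c(A = 1, B = 2, C = 2, D = 1)
  edge_w <- stats::setNames(rep(1, 5), edge_key(assoc$edges$from, assoc$edges$to))
  sc <- weighted_association(assoc, node_w, edge_w)
  expect_equal(sc$c_nw, 4 / 6)
  expect_equal(sc$c_ew, 0.2)
  expect_equal(sc$c_w, sqrt(((4 / 6)^2 + 0.2^2) / 2))
})

test_that("uniform weights reduce the weighted score to the unweighted one", {
  for (seed in 1:15) {
    fx <- synth_pathway_pair(10, 10, 4, 0.3, n_derived = 2, seed = 300 + seed)
    assoc <- build_association(fx$net_a, fx$net_b, fx$interactome)
    nodes <- assoc$nodes$node
    node_w <- stats::setNames(rep(1, length(nodes)), nodes)
    edge_w <- stats::setNames(rep(1, nrow(assoc$edges)),
                              edge_key(assoc$edges$from, assoc$edges$to))
    sc <- weighted_association(assoc, node_w, edge_w)
    expect_equal(sc$c_nw, sc$c_n, tolerance = 1e-12)
    expect_equal(sc$c_ew, sc$c_e, tolerance = 1e-12)
    expect_equal(sc$c_w, sc$c, tolerance = 1e-12)
  }
})

test_that("weighted association validates its weight tables", {
  assoc <- build_association(tri_a, tri_b)
  edge_w <- stats::setNames(rep(1, 5), edge_key(assoc$edges$from, assoc$edges$to))
  expect_error(weighted_association(assoc, c(A = 1, B = 1, C = 1), edge_w), "D")
  allz <- stats::setNames(rep(0, 4), c("A", "B", "C", "D"))
  expect_error(weighted_association(assoc, allz, edge_w), "all-zero")
  # zero weight on every shared node drives c_nw to 0
  w0 <- c(A = 1, B = 0, C = 0, D = 1)
  expect_equal(weighted_association(assoc, w0, edge_w)$c_nw, 0)
})

test_that("combine_pathways is union, identity and idempotent", {
  x <- pathway_network(rbind(c("A", "B")), name = "x")
  y <- pathway_network(rbind(c("B", "C")), name = "y")
  u <- combine_pathways(list(x, y), name = "u")
  expect_setequal(u$nodes, c("A", "B", "C"))
  expect_setequal(edge_key(u$edges$from, u$edges$to), c("A|B", "B|C"))
  one <- combine_pathways(list(x), name = "x")
  expect_equal(one$edges, x$edges)
  expect_equal(one$nodes, x$nodes)
  twice <- combine_pathways(list(x, x), name = "x")
  expect_equal(twice$edges, x$edges)
})

test_that("pairwise matrix scores every pair, finds the argmax, and is symmetric in roles", {
  idn <- pairwise_matrix(list(A = tri_a), list(A2 = tri_a))
  expect_equal(unname(idn$matrix[1, 1]), 1)

  disj <- pathway_network(nodes = c("Z1", "Z2"), name = "disjoint")
  pw <- pairwise_matrix(list(s1 = tri_a, s2 = tri_b),
                        list(p1 = tri_b, p2 = disj))
  expect_equal(unname(pw$matrix[, "p2"]), c(0, 0))
  expect_equal(pw$top_pair$process, "p1")
  expect_equal(pw$top_pair$signal, "s2")   # tri_b vs itself scores 1

  swapped <- pairwise_matrix(list(p1 = tri_b), list(s1 = tri_a))
  expect_equal(unname(swapped$matrix[1, 1]), unname(pw$matrix["s1", "p1"]))
})
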