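test_that("TSV edge lists are deduplicated, self-loops dropped, symbols uppercased", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tB", "B\tA", "B\tB"), f)
  net <- suppressMessages(read_edge_list(f, "tsv"))
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")
})

test_that("SIF rows parse, including multi-target rows", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp C"), f)
  net <- read_edge_list(f, "sif")
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)

  writeLines(c("A pp B C"), f)
  net2 <- read_edge_list(f, "sif")
  expect_setequal(edge_key(net2$edges$from, net2$edges$to),
                  c("A|B", "A|C"))
})

test_that("malformed and empty edge-list files are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A"), f)
  expect_error(read_edge_list(f, "tsv"), "line 2")
  writeLines(character(), f)
  empty <- read_edge_list(f, "tsv")
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("networks round-trip through write_edge_list / read_edge_list", {
  for (seed in 1:5) {
    net <- random_net(12, 0.3, seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_edge_list(net, f)
    back <- read_edge_list(f, "tsv")
    expect_equal(back$edges, net$edges)
    # isolated nodes are not part of a strict edge list
    expect_setequal(back$nodes,
                    unique(c(net$edges$from, net$edges$to)))
  }
})

test_that("GMT records parse in file order with uppercased, deduplicated genes", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("HIF1\tdesc\tSRC\tSTAT3\tAKT1",
               "MITO\tdesc2\tpink1\tPRKN\tPINK1"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("HIF1", "MITO"))
  expect_setequal(sets$HIF1, c("SRC", "STAT3", "AKT1"))
  expect_setequal(sets$MITO, c("PINK1", "PRKN"))

  writeLines("ONLY\ttwo", f)
  expect_error(read_gmt(f), "3 columns")
})

test_that("DEP filter applies strict inequalities on both boundaries", {
  tab <- data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                    log2fc = c(1.2, 2.0, 0.0, -0.5),
                    p_value = c(0.01, 0.2, 0.04, 0.05))
  expect_equal(filter_deps(tab), "P1")
  expect_equal(filter_deps(tab[0, ]), character())
})

test_that("DEP filter is monotone in its thresholds", {
  tab <- withr::with_seed(42, data.frame(
    protein_id = sprintf("P%03d", 1:200),
    log2fc = rnorm(200), p_value = runif(200)))
  base <- filter_deps(tab, p_max = 0.05, min_abs_lfc = 0.5)
  wider_p <- filter_deps(tab, p_max = 0.2, min_abs_lfc = 0.5)
  wider_lfc <- filter_deps(tab, p_max = 0.05, min_abs_lfc = 0.1)
  expect_true(all(base %in% wider_p))
  expect_true(all(base %in% wider_lfc))
})

test_that("quant table reader validates its contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tlog2fc\tp_value", "P1\t0.5\t0.01", "P1\t0.2\t0.2"), f)
  expect_error(read_quant_table(f), "duplicate")
  writeLines(c("protein_id\tlog2fc\tp_value", "P1\t0.5\t1.5"), f)
  expect_error(read_quant_table(f), "p_value")
})

test_that("synthetic pathway pairs are reproducible and structurally exact", {
  f1 <- synth_pathway_pair(5, 5, 2, 0.5, 3, seed = 7)
  f2 <- synth_pathway_pair(5, 5, 2, 0.5, 3, seed = 7)
  expect_identical(f1, f2)
  expect_equal(length(intersect(f1$net_a$nodes, f1$net_b$nodes)), 2L)

  # interactome always contains both pathway edge sets; derived count exact
  for (seed in 1:10) {
    fx <- synth_pathway_pair(8, 10, 3, 0.4, 5, seed = seed)
    ik <- edge_key(fx$interactome$edges$from, fx$interactome$edges$to)
    ka <- edge_key(fx$net_a$edges$from, fx$net_a$edges$to)
    kb <- edge_key(fx$net_b$edges$from, fx$net_b$edges$to)
    expect_true(all(c(ka, kb) %in% ik))
    expect_equal(length(setdiff(ik, union(ka, kb))), 5L)
  }

  # no derived edges requested: interactome equals the pathway edge union
  fx0 <- synth_pathway_pair(6, 6, 0, 0.5, 0, seed = 3)
  ik0 <- edge_key(fx0$interactome$edges$from, fx0$interactome$edges$to)
  expect_setequal(ik0, union(edge_key(fx0$net_a$edges$from, fx0$net_a$edges$to),
                             edge_key(fx0$net_b$edges$from, fx0$net_b$edges$to)))
})

test_that("infeasible derived-edge requests error explicitly", {
  expect_error(synth_pathway_pair(3, 3, 3, 1, 100, seed = 1), "n_derived")
})

test_that("weight tables read node and edge dialects with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t1.5", "B\t0"), f)
  w <- read_weight_table(f)
  expect_equal(w, c(A = 1.5, B = 0))
  writeLines(c("B\tA\t2", "A\tC\t1"), f)
  we <- read_weight_table(f)
  expect_equal(we[["A|B"]], 2)
  writeLines(c("A\tB\t1", "B\tA\t2"), f)
  expect_error(read_weight_table(f), "duplicate")
  writeLines("A\t-1", f)
  expect_error(read_weight_table(f), "nonnegative")
})
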