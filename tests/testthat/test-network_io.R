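test_that("edge-list parsing canonicalizes duplicates, reversals and self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "B\tC"), f)
  net <- read_edge_list(f)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$from, c("A", "B"))
  expect_equal(net$edges$to, c("B", "C"))

  writeLines(c("A\tA", "A\tB"), f)
  expect_warning(net <- read_edge_list(f), "self-loop")
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(net$nodes, c("A", "B"))

  # 5 rows forming a 6-node path
  nodes <- LETTERS[1:6]
  writeLines(paste(nodes[-6], nodes[-1], sep = "\t"), f)
  net <- read_edge_list(f)
  expect_length(net$nodes, 6L)
  expect_equal(nrow(net$edges), 5L)
})

test_that("edge-list parsing reports malformed rows by line number and rejects empty input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tB", "oops"), f)
  expect_error(read_edge_list(f), "line 3")
  writeLines(c("A\tB\tnotanumber"), f)
  expect_error(read_edge_list(f), "non-numeric weight at line 1")
  writeLines(c("# only comments"), f)
  expect_error(read_edge_list(f), "no data rows")
  writeLines(c("src\ttgt"), f)
  expect_error(read_edge_list(f, has_header = TRUE), "no data rows")
})

test_that("edge-list write/read round trip is idempotent on the canonical form", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("B\tA", "C\tB", "A\tB", "D\tC\t2.5"), f)
  net1 <- read_edge_list(f)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net1, g)
  net2 <- read_edge_list(g)
  expect_identical(net1$edges, net2$edges)
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(network_fingerprint(net1), network_fingerprint(net2))
})

test_that("adjacency is symmetric with zero diagonal on random graphs", {
  for (s in 1:5) {
    net <- rand_connected_net(60, seed = s)
    A <- net$adjacency
    expect_equal(as.matrix(A), t(as.matrix(A)))
    expect_true(all(Matrix::diag(A) == 0))
    expect_true(all(A@x >= 0))
  }
})

test_that("main component extraction keeps the largest component with lexicographic ties", {
  net <- gene_network(data.frame(from = c("A", "B", "D"), to = c("B", "C", "E")))
  mc <- main_component(net)
  expect_setequal(mc$nodes, c("A", "B", "C"))

  conn <- path_net(LETTERS[1:4])
  expect_identical(main_component(conn)$edges, conn$edges)

  tie <- gene_network(data.frame(from = c("C", "A"), to = c("D", "B")))
  expect_setequal(main_component(tie)$nodes, c("A", "B"))

  # output is at least as large as any component of the input
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(80, 1.5 / 80)
    el <- igraph::as_edgelist(g, names = FALSE)
    if (!nrow(el)) next
    net <- gene_network(data.frame(from = sprintf("N%02d", el[, 1]),
                                   to = sprintf("N%02d", el[, 2])))
    comp <- igraph::components(igraph::graph_from_data_frame(net$edges[, 1:2],
                                                             directed = FALSE))
    expect_equal(length(main_component(net)$nodes), max(comp$csize))
  }
})

test_that("gene sets parse from plain and GMT formats with dedup and error contracts", {
  f <- withr::local_tempfile(pattern = "dge", fileext = ".txt")
  writeLines(c("g1", "g2", "g1"), f)
  sets <- read_gene_sets(f, "plain")
  expect_length(sets, 1L)
  expect_equal(sets[[1L]]$name, basename(tools::file_path_sans_ext(f)))
  expect_equal(sets[[1L]]$genes, c("g1", "g2"))

  g <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\ta\tb\tc", "S2\tdesc\tx\ty"), g)
  sets <- read_gene_sets(g, "gmt")
  expect_equal(names(sets), c("S1", "S2"))
  expect_equal(sets$S1$genes, c("a", "b", "c"))
  expect_equal(sets$S2$genes, c("x", "y"))

  writeLines(c("S1\tdesc\ta", "S1\tdesc\tb"), g)
  expect_error(read_gene_sets(g, "gmt"), "duplicate")
  writeLines(character(0), f)
  expect_error(read_gene_sets(f, "plain"), "empty")
  expect_error(gene_set("empty", character(0)), "empty")

  # round trip through GMT
  sets <- list(A = gene_set("A", c("g1", "g2")), B = gene_set("B", "g9"))
  write_gene_sets(sets, g)
  back <- read_gene_sets(g, "gmt")
  expect_equal(lapply(back, `[[`, "genes"), lapply(sets, `[[`, "genes"))
})
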