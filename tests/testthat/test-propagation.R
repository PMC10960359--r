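test_that("seed vectors place 1/s on present seeds and handle absent genes", {
  net <- path_net(c("A", "B", "C"))
  expect_equal(unname(build_seed_vector(net, c("A", "B"))), c(0.5, 0.5, 0))
  expect_warning(y <- build_seed_vector(net, gene_set("s", c("A", "X"))),
                 "absent")
  expect_equal(unname(y), c(1, 0, 0))
  expect_equal(sum(y), 1)
  expect_error(build_seed_vector(net, gene_set("ghost", "X")), "ghost")
})

test_that("adjacency normalization matches hand-computed operators", {
  two <- edge_net("A", "B")
  expect_equal(as.matrix(normalize_adjacency(two, "symmetric")),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))
  pth <- path_net(c("A", "B", "C"))
  Wsym <- as.matrix(normalize_adjacency(pth, "symmetric"))
  expect_equal(Wsym["A", "B"], 1 / sqrt(2))
  expect_equal(Wsym["B", "C"], 1 / sqrt(2))
  Wrow <- as.matrix(normalize_adjacency(pth, "row_stochastic"))
  expect_equal(unname(Wrow["B", ]), c(0.5, 0, 0.5))
  expect_equal(unname(Wrow["A", ]), c(0, 1, 0))
})

test_that("propagation reproduces the closed-form solution of the restart equation", {
  # independent oracle: dense linear algebra on the hand-built operator
  net <- edge_net("A", "B")
  cfg <- propagation_config(alpha = 0.8)
  y <- build_seed_vector(net, "A")
  expected <- solve(diag(2) - 0.8 * matrix(c(0, 1, 1, 0), 2), 0.2 * c(1, 0))
  f <- propagate(net, y, cfg)
  expect_equal(unname(as.numeric(f)), expected, tolerance = 1e-6)
  expect_equal(unname(as.numeric(f)), c(0.5556, 0.4444), tolerance = 1e-3)

  # restart-dominated limit: alpha ~ 0 returns the seed vector
  tiny <- propagation_config(alpha = 1e-12)
  expect_equal(as.numeric(propagate(net, y, tiny)), c(1, 0), tolerance = 1e-9)

  # mass conservation of the row-stochastic operator under the uniform seed
  net2 <- rand_connected_net(40, seed = 3)
  n <- length(net2$nodes)
  uni <- stats::setNames(rep(1 / n, n), net2$nodes)
  frs <- propagate(net2, uni, propagation_config(operator_norm = "row_stochastic"))
  expect_equal(sum(frs), 1, tolerance = 1e-9)
})

test_that("iterative and direct propagation agree, scores stay positive, residuals contract", {
  for (s in 1:10) {
    net <- rand_connected_net(50, seed = s)
    y <- build_seed_vector(net, net$nodes[1L])
    for (a in c(0.5, 0.8)) {
      cfg <- propagation_config(alpha = a)
      fi <- propagate(net, y, cfg)
      fd <- propagate_direct(net, y, cfg)
      expect_lt(max(abs(fi - fd)), 1e-6)
      expect_true(all(as.numeric(fi) > 0))
      r <- attr(fi, "residuals")
      expect_true(all(diff(r) <= 1e-15))
    }
  }
})

test_that("automorphic nodes receive equal scores and the alpha series limit holds", {
  pth <- path_net(c("A", "B", "C"))
  y <- build_seed_vector(pth, "B")
  f <- propagate(pth, y, propagation_config())
  expect_equal(f[["A"]], f[["C"]])
  # small-alpha expansion of the direct solve: F = (1-a)Y + O(a)
  a <- 1e-4
  fd <- propagate_direct(pth, y, propagation_config(alpha = a))
  expect_equal(unname(as.numeric(fd)), unname((1 - a) * y), tolerance = 1e-3)
})

test_that("propagation errors on non-convergence and direct solve guards its size", {
  net <- rand_connected_net(30, seed = 1)
  y <- build_seed_vector(net, net$nodes[1L])
  expect_error(propagate(net, y, propagation_config(tol = 1e-14, max_iter = 3L)),
               "converge")
  big <- structure(list(nodes = sprintf("N%d", 1:5001)), class = "gene_network")
  y2 <- stats::setNames(c(1, numeric(5000)), big$nodes)
  expect_error(propagate_direct(big, y2, propagation_config()), "5000")
})

test_that("degree-bias normalization divides by the uniform baseline", {
  net <- edge_net("A", "B")
  cfg <- propagation_config()
  raw <- propagate(net, build_seed_vector(net, "A"), cfg)
  norm <- normalize_scores(raw, net, cfg)
  expect_equal(unname(as.numeric(norm)), c(1.1111, 0.8889), tolerance = 1e-3)

  # regular graph: constant baseline, so ranking is unchanged
  cyc <- gene_network(data.frame(from = c("A", "B", "C", "D"),
                                 to = c("B", "C", "D", "A")))
  raw <- propagate(cyc, build_seed_vector(cyc, "A"), cfg)
  norm <- normalize_scores(raw, cyc, cfg)
  expect_equal(order(-as.numeric(norm)), order(-as.numeric(raw)))

  # self-normalization: the uniform seed divided by its own baseline is 1
  n <- length(cyc$nodes)
  uni <- stats::setNames(rep(1 / n, n), cyc$nodes)
  expect_equal(unname(as.numeric(normalize_scores(propagate(cyc, uni, cfg), cyc, cfg))),
               rep(1, n), tolerance = 1e-6)

  # mismatched node order is rejected
  shuffled <- rev(as.numeric(raw))
  names(shuffled) <- rev(names(raw))
  expect_error(normalize_scores(shuffled, cyc, cfg), "aligned")
})

test_that("score TSVs round-trip through write_scores/read_scores", {
  net <- rand_connected_net(30, seed = 5)
  f <- propagate(net, build_seed_vector(net, net$nodes[2L]), propagation_config())
  p <- withr::local_tempfile(fileext = ".tsv")
  write_scores(f, p)
  back <- read_scores(p)
  expect_equal(back[names(f)], stats::setNames(as.numeric(f), names(f)),
               tolerance = 1e-12)
  # sorted by descending score
  expect_true(!is.unsorted(rev(unname(back))))
})
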