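test_that("AUROC and AUPRC match independent references", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    n <- 40L
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2L) next
    scores <- rnorm(n) + labels # some signal, plus ties occasionally
    if (i %% 2 == 0) scores <- round(scores, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
    expect_equal(auprc(scores, labels), brute_auprc(scores, labels),
                 tolerance = 1e-12)
  }
  # degenerate ranking sanity
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(auprc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
})

test_that("negative sampling draws the requested count from the eligible pool", {
  universe <- sprintf("g%03d", 1:100)
  pos <- gene_set("pos", universe[1:10])
  excl <- gene_set("excl", universe[1:20])
  spec <- label_spec(pos, excl, rng_seed = 5)
  neg <- sample_negatives(universe, spec)
  expect_length(neg$genes, 10L)
  expect_true(all(neg$genes %in% universe[21:100]))
  expect_identical(sample_negatives(universe, spec)$genes, neg$genes)
  expect_length(sample_negatives(universe, label_spec(pos, excl, 2, 5))$genes, 20L)
  expect_error(sample_negatives(universe[1:25], label_spec(pos, excl, 10, 5)),
               "pool too small")
  expect_error(label_spec(pos, gene_set("e", universe[5:20])), "every positive")
})

test_that("a perfectly separable toy problem is classified perfectly", {
  genes <- sprintf("g%02d", 1:40)
  vals <- matrix(rep(c(1, 0), each = 20), ncol = 2, nrow = 40,
                 dimnames = list(genes, c("f1", "f2")))
  vals[, 2] <- rev(vals[, 1])
  fm <- toy_features(vals)
  labels <- list(positives = genes[1:20], negatives = genes[21:40])
  cv <- cross_validate(fm, labels, forest_config(rng_seed = 1))
  expect_equal(cv$mean_auroc, 1)
  expect_equal(cv$mean_auprc, 1)

  model <- train_full(fm, labels, forest_config(rng_seed = 1))
  sc <- predict_scores(model, fm)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(min(sc[genes[1:20]]), max(sc[genes[21:40]]))
})

test_that("fold bookkeeping: stratified partition, exact means, determinism", {
  set.seed(77)
  genes <- sprintf("g%03d", 1:120)
  vals <- matrix(rnorm(240), ncol = 2, dimnames = list(genes, c("a", "b")))
  vals[1:60, ] <- vals[1:60, ] + 1
  fm <- toy_features(vals)
  labels <- list(positives = genes[1:60], negatives = genes[61:120])
  cv <- cross_validate(fm, labels, forest_config(rng_seed = 3), folds = 5L)

  # partition: every labeled gene in exactly one test fold, stratified
  expect_setequal(names(cv$fold_assignment), genes)
  expect_true(all(table(cv$fold_assignment) == 24L))
  for (k in 1:5) {
    in_fold <- names(cv$fold_assignment)[cv$fold_assignment == k]
    expect_equal(sum(cv$labels[in_fold] == 1L), 12L)
  }
  expect_true(all(!is.na(cv$oof_scores)))

  # means are the arithmetic means of per-fold areas, exactly
  expect_identical(cv$mean_auroc,
                   mean(vapply(cv$per_fold, `[[`, numeric(1), "auroc")))
  expect_identical(cv$mean_auprc,
                   mean(vapply(cv$per_fold, `[[`, numeric(1), "auprc")))

  # fixed seeds reproduce the whole result
  cv2 <- cross_validate(fm, labels, forest_config(rng_seed = 3), folds = 5L)
  expect_equal(cv, cv2)

  # mean curves live on the 101-point grid
  expect_equal(nrow(cv$mean_roc), 101L)
  expect_true(all(diff(cv$mean_roc$tpr) >= 0))
})

test_that("labeled genes missing from the feature matrix are reported", {
  genes <- sprintf("g%02d", 1:20)
  fm <- toy_features(matrix(rnorm(20), ncol = 1, dimnames = list(genes, "f")))
  labels <- list(positives = c(genes[1:6], "absent1"), negatives = genes[7:12])
  expect_error(cross_validate(fm, labels, forest_config()), "absent1")
})

test_that("trained models persist and reload with identical predictions", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:60)
  vals <- matrix(rnorm(120), ncol = 2, dimnames = list(genes, c("a", "b")))
  vals[1:30, ] <- vals[1:30, ] + 2
  fm <- toy_features(vals)
  labels <- list(positives = genes[1:30], negatives = genes[31:60])
  model <- train_full(fm, labels, forest_config(rng_seed = 9))
  before <- predict_scores(model, fm)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(model, p)
  after <- predict_scores(load_model(p), fm)
  expect_identical(unname(as.numeric(before)), unname(as.numeric(after)))

  # mismatched feature columns are rejected
  fm2 <- fm
  fm2$set_names <- c("x", "y")
  colnames(fm2$values) <- c("x", "y")
  expect_error(predict_scores(model, fm2), "columns do not match")
})
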