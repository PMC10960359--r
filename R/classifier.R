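#' Label specification for training
#'
#' Positives are the curated high-confidence disease genes; negatives are
#' sampled uniformly from genes outside the exclusion list (typically the
#' whole curated database, so that weaker candidates are never labelled
#' negative). `negative_ratio` controls class balance: 1.0 reproduces the
#' balanced positives:negatives design.
#'
#' @param positives a [gene_set()] of positive-label genes.
#' @param exclusion a [gene_set()] of genes ineligible as negatives; must
#'   contain all positives.
#' @param negative_ratio negatives per in-network positive, default 1.
#' @param rng_seed integer seed for negative sampling.
#' @return An object of class `label_spec`.
#' @export
label_spec <- function(positives, exclusion = positives, negative_ratio = 1,
                       rng_seed = 1L) {
  stopifnot(inherits(positives, "gene_set"), inherits(exclusion, "gene_set"),
            negative_ratio > 0)
  if (!all(positives$genes %in% exclusion$genes)) {
    stop_data("exclusion list must contain every positive gene")
  }
  structure(list(positives = positives, exclusion = exclusion,
                 negative_ratio = negative_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "label_spec")
}

#' Random-forest settings
#'
#' Defaults mirror the conventional forest configuration for this task:
#' 100 trees, no depth limit, nodes split down to purity.
#'
#' @param n_trees number of trees, default 100.
#' @param rng_seed integer seed governing fold assignment and tree
#'   randomness.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, rng_seed = 1L) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), rng_seed = as.integer(rng_seed)),
            class = "forest_config")
}

#' Sample negative-label genes
#'
#' Uniform sample without replacement from the universe minus the
#' exclusion list, of size `round(negative_ratio * #positives present)`.
#' Reproducible under the spec's `rng_seed`.
#'
#' @param universe a `gene_network` or character vector of gene
#'   identifiers defining the scored universe.
#' @param spec a [label_spec()].
#' @return A [gene_set()] named `"negatives"`.
#' @export
sample_negatives <- function(universe, spec) {
  stopifnot(inherits(spec, "label_spec"))
  genes <- if (inherits(universe, "gene_network")) universe$nodes else as.character(universe)
  pool <- setdiff(genes, spec$exclusion$genes)
  n_pos <- sum(spec$positives$genes %in% genes)
  if (n_pos == 0L) stop_data("no positive gene is present in the universe")
  k <- round(spec$negative_ratio * n_pos)
  if (length(pool) < k) {
    stop_data(sprintf("negative pool too small: need %d, have %d eligible of %d genes",
                      k, length(pool), length(genes)))
  }
  with_rng(spec$rng_seed, gene_set("negatives", sample(pool, k)))
}

# Resolve a label_spec (or explicit list(positives=, negatives=)) against a
# feature matrix into aligned vectors. Explicit labeled genes missing from
# the matrix are an error; label_spec positives off the universe are
# dropped with a warning (curated lists routinely exceed the network).
resolve_labels <- function(features, labels) {
  stopifnot(inherits(features, "feature_matrix"))
  if (inherits(labels, "label_spec")) {
    pos <- intersect(labels$positives$genes, features$genes)
    dropped <- setdiff(labels$positives$genes, pos)
    if (length(dropped)) {
      warning(sprintf("%d positive gene(s) absent from the feature matrix and dropped",
                      length(dropped)), call. = FALSE)
    }
    if (!length(pos)) stop_data("no positive gene is present in the feature matrix")
    neg <- sample_negatives(features$genes, labels)$genes
  } else if (is.list(labels) && all(c("positives", "negatives") %in% names(labels))) {
    pos <- if (inherits(labels$positives, "gene_set")) labels$positives$genes else as.character(labels$positives)
    neg <- if (inherits(labels$negatives, "gene_set")) labels$negatives$genes else as.character(labels$negatives)
    missing <- setdiff(c(pos, neg), features$genes)
    if (length(missing)) {
      stop_data("labeled gene(s) absent from the feature matrix: ",
                paste(utils::head(missing, 10L), collapse = ", "))
    }
  } else {
    stop_data("labels must be a label_spec or a list with positives and negatives")
  }
  if (length(intersect(pos, neg))) stop_data("positive and negative sets overlap")
  list(genes = c(pos, neg),
       label = c(rep(1L, length(pos)), rep(0L, length(neg))))
}

fit_forest <- function(x, y, forest) {
  randomForest::randomForest(
    x = x, y = y, ntree = forest$n_trees,
    nodesize = 1L # split to purity, no depth cap
  )
}

#' Stratified k-fold cross-validation of the forest
#'
#' Negatives are sampled once per experiment (when `labels` is a
#' [label_spec()]); labeled genes are then partitioned into `folds`
#' stratified folds. Each fold's model is trained on the remaining folds
#' and scores the held-out genes with the positive-class vote fraction.
#' Mean AUROC/AUPRC are the arithmetic means of the per-fold areas; mean
#' ROC/PR curves are additionally vertically averaged on a common
#' 101-point grid for plotting.
#'
#' @param features a `feature_matrix`.
#' @param labels a [label_spec()], or a list with elements `positives`
#'   and `negatives` (gene sets or character vectors) for explicit labels.
#' @param forest a [forest_config()].
#' @param folds number of folds, default 5.
#' @return An object of class `cv_result`: `per_fold` (per-fold list of
#'   `auroc`, `auprc`, `roc`, `pr`), `mean_auroc`, `mean_auprc`,
#'   `mean_roc`, `mean_pr`, `oof_scores` (out-of-fold score per labeled
#'   gene), `labels`, and `fold_assignment`.
#' @export
cross_validate <- function(features, labels, forest = forest_config(),
                           folds = 5L) {
  stopifnot(inherits(forest, "forest_config"), folds >= 2L)
  lab <- resolve_labels(features, labels)
  genes <- lab$genes
  y <- factor(ifelse(lab$label == 1L, "pos", "neg"), levels = c("neg", "pos"))
  if (min(table(y)) < folds) {
    stop_data("need at least ", folds, " genes of each class for ", folds, "-fold CV")
  }
  x <- features$values[genes, , drop = FALSE]

  with_rng(forest$rng_seed, {
    fold_id <- integer(length(genes))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    oof <- stats::setNames(rep(NA_real_, length(genes)), genes)
    per_fold <- vector("list", folds)
    for (k in seq_len(folds)) {
      test <- fold_id == k
      fit <- fit_forest(x[!test, , drop = FALSE], y[!test], forest)
      sc <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")[, "pos"]
      oof[test] <- sc
      per_fold[[k]] <- list(
        auroc = auroc(sc, y[test] == "pos"),
        auprc = auprc(sc, y[test] == "pos"),
        roc = roc_points(sc, y[test] == "pos"),
        pr = pr_points(sc, y[test] == "pos")
      )
    }
  })
  structure(
    list(per_fold = per_fold,
         mean_auroc = mean(vapply(per_fold, `[[`, numeric(1L), "auroc")),
         mean_auprc = mean(vapply(per_fold, `[[`, numeric(1L), "auprc")),
         mean_roc = mean_curve(lapply(per_fold, `[[`, "roc"), "fpr", "tpr"),
         mean_pr = mean_curve(lapply(per_fold, `[[`, "pr"), "recall", "precision"),
         oof_scores = oof,
         labels = stats::setNames(lab$label, genes),
         fold_assignment = stats::setNames(fold_id, genes),
         folds = folds),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV on %d labeled genes: mean AUROC %.3f, mean AUPRC %.3f\n",
              x$folds, length(x$labels), x$mean_auroc, x$mean_auprc))
  invisible(x)
}

#' Train the forest on all labeled genes
#'
#' @inheritParams cross_validate
#' @return An object of class `propforest_model` wrapping the fitted
#'   forest, the feature column names, and the training labels.
#' @export
train_full <- function(features, labels, forest = forest_config()) {
  stopifnot(inherits(forest, "forest_config"))
  lab <- resolve_labels(features, labels)
  y <- factor(ifelse(lab$label == 1L, "pos", "neg"), levels = c("neg", "pos"))
  x <- features$values[lab$genes, , drop = FALSE]
  fit <- with_rng(forest$rng_seed, fit_forest(x, y, forest))
  structure(list(forest = fit, feature_names = features$set_names,
                 training_genes = lab$genes,
                 training_labels = stats::setNames(lab$label, lab$genes),
                 config = forest),
            class = "propforest_model")
}

#' @export
print.propforest_model <- function(x, ...) {
  cat(sprintf("<propforest_model> %d trees on %d genes x %d features\n",
              x$config$n_trees, length(x$training_genes),
              length(x$feature_names)))
  invisible(x)
}

#' Score genes with a trained model
#'
#' Every gene in the feature matrix receives the positive-class vote
#' fraction in \[0, 1\].
#'
#' @param model a `propforest_model` from [train_full()].
#' @param features a `feature_matrix` with the same columns the model was
#'   trained on.
#' @return Named numeric score vector (`kind` attribute `"classifier"`).
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "propforest_model"), inherits(features, "feature_matrix"))
  if (!identical(features$set_names, model$feature_names)) {
    stop_data("feature columns do not match the model: expected (",
              paste(model$feature_names, collapse = ", "), "), got (",
              paste(features$set_names, collapse = ", "), ")")
  }
  sc <- stats::predict(model$forest, features$values, type = "prob")[, "pos"]
  score_vector(stats::setNames(as.numeric(sc), features$genes), "classifier")
}

#' Persist / restore a trained model
#'
#' Round trip preserves predictions exactly.
#'
#' @param model a `propforest_model`.
#' @param path file path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "propforest_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "propforest_model")) stop_data("not a propforest model: ", path)
  model
}
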