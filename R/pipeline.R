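#' Assemble a full pipeline configuration
#'
#' Collects file paths and stage settings for [run_pipeline()]. Inputs
#' may be given as paths (read in the package's standard formats) or as
#' in-memory objects from [generate_benchmark()].
#'
#' @param network a `gene_network` or edge-list TSV path.
#' @param seed_sets named list of [gene_set()], or a GMT path.
#' @param positives a [gene_set()] or plain-text path.
#' @param exclusion a [gene_set()] or plain-text path; defaults to the
#'   positives.
#' @param out_dir output directory.
#' @param propagation a [propagation_config()].
#' @param forest a [forest_config()].
#' @param negative_ratio negatives per in-network positive.
#' @param folds CV folds, default 5.
#' @param network_null randomize the network (degree-preserving) before
#'   propagation — the negative-control arm.
#' @param swaps_per_edge swap budget for the null arm.
#' @param group_tests optional named list of gene vectors; each is
#'   rank-tested against random genes on the final scores.
#' @param rng_seed global seed; stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(network, seed_sets, positives, exclusion = NULL,
                       out_dir = NULL,
                       propagation = propagation_config(),
                       forest = NULL, negative_ratio = 1, folds = 5L,
                       network_null = FALSE, swaps_per_edge = 10,
                       group_tests = NULL, rng_seed = 1L) {
  rng_seed <- as.integer(rng_seed)
  structure(list(network = network, seed_sets = seed_sets,
                 positives = positives, exclusion = exclusion,
                 out_dir = out_dir, propagation = propagation,
                 forest = forest %||% forest_config(rng_seed = rng_seed + 2L),
                 negative_ratio = negative_ratio, folds = as.integer(folds),
                 network_null = isTRUE(network_null),
                 swaps_per_edge = swaps_per_edge,
                 group_tests = group_tests, rng_seed = rng_seed),
            class = "run_config")
}

load_input <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1L && !inherits(x, "AsIs")) {
    if (!file.exists(x)) stop_data(what, " file not found: ", x)
    reader(x)
  } else {
    x
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_data(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full prioritization pipeline
#'
#' Wires the stages end to end: main-component extraction (optionally on
#' a degree-preserving randomized copy of the network for the
#' negative-control arm), per-list propagation and normalization into a
#' feature matrix, stratified cross-validation, full-model training,
#' genome-wide scoring, operating-cutoff selection on the out-of-fold
#' scores under both criteria, and optional group rank tests. All
#' randomness derives from `cfg$rng_seed`, so two runs with the same
#' configuration produce identical outputs; a JSON manifest records the
#' configuration, seeds and network fingerprint.
#'
#' @param cfg a [run_config()].
#' @return A report list with elements `network`, `features`, `cv`,
#'   `model`, `scores` (full-model genome-wide), `oof_scores`,
#'   `cutoff_spec_sens`, `cutoff_prec_rec`, `group_tests`, `manifest`
#'   (plus written files under `cfg$out_dir` when set).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  net <- stage("network_io", {
    n <- load_input(cfg$network, read_edge_list, "network")
    main_component(n)
  })
  retained <- NA_real_
  if (cfg$network_null) {
    net <- stage("randomization", {
      full <- degree_preserving_randomize(net, swaps_per_edge = cfg$swaps_per_edge,
                                          rng_seed = cfg$rng_seed + 1L)
      comp <- main_component(full)
      retained <<- length(comp$nodes) / length(full$nodes)
      message(sprintf("network-null arm: retained %.1f%% of nodes in the main component after randomization",
                      100 * retained))
      comp
    })
  }
  seed_sets <- stage("seed_sets", {
    s <- load_input(cfg$seed_sets, function(p) read_gene_sets(p, "gmt"), "seed set")
    if (inherits(s, "gene_set")) s <- stats::setNames(list(s), s$name)
    s
  })
  positives <- stage("labels", {
    p <- load_input(cfg$positives, function(p) read_gene_sets(p, "plain")[[1L]], "positives")
    if (!inherits(p, "gene_set")) p <- gene_set("positives", p)
    p
  })
  exclusion <- stage("labels", {
    e <- cfg$exclusion %||% positives
    e <- load_input(e, function(p) read_gene_sets(p, "plain")[[1L]], "exclusion")
    if (!inherits(e, "gene_set")) e <- gene_set("exclusion", e)
    if (!all(positives$genes %in% e$genes)) {
      e <- gene_set(e$name, c(e$genes, positives$genes))
    }
    e
  })
  # curated positives routinely extend beyond the network; restrict up front
  pos_in_net <- intersect(positives$genes, net$nodes)
  if (!length(pos_in_net)) stop_data("pipeline stage 'labels' failed: no positive gene in the network")
  if (length(pos_in_net) < length(positives$genes)) {
    message(sprintf("%d of %d positive genes are outside the network and were dropped",
                    length(positives$genes) - length(pos_in_net), length(positives$genes)))
  }
  positives <- gene_set(positives$name, pos_in_net)
  labels <- label_spec(positives, exclusion, negative_ratio = cfg$negative_ratio,
                       rng_seed = cfg$rng_seed)

  features <- stage("features", build_feature_matrix(net, seed_sets, cfg$propagation))
  cv <- stage("classifier", cross_validate(features, labels, cfg$forest, cfg$folds))
  model <- stage("classifier", train_full(features, labels, cfg$forest))
  scores <- stage("classifier", predict_scores(model, features))
  cut_ss <- stage("evaluation", optimal_cutoff(cv$oof_scores, cv$labels, "spec_times_sens"))
  cut_pr <- stage("evaluation", optimal_cutoff(cv$oof_scores, cv$labels, "prec_plus_rec"))
  group_tests <- NULL
  if (length(cfg$group_tests)) {
    group_tests <- stage("evaluation", {
      res <- lapply(seq_along(cfg$group_tests), function(i) {
        group_rank_test(scores, cfg$group_tests[[i]],
                        rng_seed = cfg$rng_seed + 10L + i)
      })
      stats::setNames(res, names(cfg$group_tests))
    })
  }
  fp <- network_fingerprint(net)
  manifest <- list(
    package_version = as.character(utils::packageVersion("propforest")),
    rng_seed = cfg$rng_seed,
    propagation = unclass(cfg$propagation),
    forest = unclass(cfg$forest),
    folds = cfg$folds, negative_ratio = cfg$negative_ratio,
    network_null = cfg$network_null,
    null_retained_fraction = if (cfg$network_null) retained else NULL,
    network = fp,
    n_seed_lists = length(seed_sets),
    n_positives = length(positives$genes),
    mean_auroc = cv$mean_auroc, mean_auprc = cv$mean_auprc,
    cutoff_spec_times_sens = cut_ss$cutoff,
    cutoff_prec_plus_rec = cut_pr$cutoff
  )
  report <- list(network = net, features = features, cv = cv, model = model,
                 scores = scores, oof_scores = cv$oof_scores,
                 cutoff_spec_sens = cut_ss, cutoff_prec_rec = cut_pr,
                 group_tests = group_tests, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir, cv)
  report
}

write_report <- function(report, dir, cv) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(report$features, file.path(dir, "feature_matrix.tsv"))
  write_scores(report$scores, file.path(dir, "scores_full_model.tsv"))
  write_scores(cv$oof_scores, file.path(dir, "scores_out_of_fold.tsv"))
  per_fold <- data.frame(
    fold = seq_along(cv$per_fold),
    auroc = vapply(cv$per_fold, `[[`, numeric(1L), "auroc"),
    auprc = vapply(cv$per_fold, `[[`, numeric(1L), "auprc")
  )
  utils::write.table(per_fold, file.path(dir, "cv_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$mean_roc, file.path(dir, "mean_roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cv$mean_pr, file.path(dir, "mean_pr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
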