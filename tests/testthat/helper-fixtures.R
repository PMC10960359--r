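# Fixtures are built in code; no files are shipped.

# Simple path graph over the given node names.
path_net <- function(nodes) {
  gene_network(data.frame(from = nodes[-length(nodes)], to = nodes[-1L]))
}

edge_net <- function(from, to, weight = NULL) {
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- weight
  gene_network(df)
}

# Main component of an Erdos-Renyi graph; used as "random connected graph".
rand_connected_net <- function(n, p = 4 / n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g, names = FALSE)
  main_component(gene_network(data.frame(from = sprintf("N%04d", el[, 1L]),
                                         to = sprintf("N%04d", el[, 2L]))))
}

# Heavy-tailed (power-law-ish) random graph via a static fitness model.
heavy_tailed_net <- function(n, m = 3L * n, exponent = 2.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_fitness_pl(n, m, exponent.out = exponent)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  main_component(gene_network(data.frame(from = sprintf("N%04d", el[, 1L]),
                                         to = sprintf("N%04d", el[, 2L]))))
}

# Hand-built feature matrix for classifier tests.
toy_features <- function(values) {
  structure(list(genes = rownames(values), set_names = colnames(values),
                 values = values,
                 provenance = list(alpha = 0.8, tol = 1e-8,
                                   operator_norm = "symmetric",
                                   n_nodes = nrow(values), n_edges = 0L,
                                   hash = "00000000")),
            class = "feature_matrix")
}

# Independent brute-force oracle for optimal_cutoff: naive loop over every
# distinct observed score, recomputing the confusion table from scratch.
brute_cutoff <- function(scores, labels, criterion) {
  labels <- as.integer(as.logical(labels))
  best <- list(value = -Inf, cutoff = NA_real_)
  for (cand in sort(unique(scores))) {
    pred <- scores >= cand
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    value <- if (criterion == "spec_times_sens") sens * spec else prec + sens
    if (value > best$value + 1e-12) best <- list(value = value, cutoff = cand)
  }
  best
}

# Brute-force average precision: enumerate prediction ranks directly.
brute_auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  total <- 0
  prev_recall <- 0
  n_pos <- sum(labels)
  for (cand in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= cand
    tp <- sum(pred & labels == 1L)
    prec <- tp / sum(pred)
    recall <- tp / n_pos
    total <- total + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  total
}

# Run the planted-module benchmark end to end and return the mean CV AUROC.
bench_auroc <- function(frac, gseed, null_net = FALSE, permute = FALSE,
                        n_nodes = 2000L) {
  b <- generate_benchmark(benchmark_config(n_nodes = n_nodes,
                                           seed_overlap_frac = frac,
                                           rng_seed = gseed))
  net <- b$network
  if (null_net) {
    net <- main_component(degree_preserving_randomize(net, rng_seed = gseed + 1L))
  }
  fm <- build_feature_matrix(net, b$seed_sets)
  pos <- intersect(b$positives$genes, net$nodes)
  spec <- label_spec(gene_set("pos", pos), b$exclusion, rng_seed = gseed)
  labels <- spec
  if (permute) {
    neg <- sample_negatives(net$nodes, spec)$genes
    set.seed(gseed + 99L)
    shuffled <- sample(c(pos, neg))
    labels <- list(positives = shuffled[seq_along(pos)],
                   negatives = shuffled[-seq_along(pos)])
  }
  cross_validate(fm, labels, forest_config(rng_seed = gseed))$mean_auroc
}
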