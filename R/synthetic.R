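#' Synthetic benchmark settings
#'
#' Defines the planted-module study conditions used throughout the test
#' suite: a preferential-attachment network (heavy-tailed degrees, like
#' real protein interaction networks), a planted disease module, seed
#' lists that mix module and background genes, and positive labels drawn
#' from the module. By default the module is a bare node set, so the
#' recoverable signal flows through seed-list overlap with the module;
#' `module_edge_prob` optionally densifies the module's internal edges to
#' add a topological component to the signal (at the cost of making
#' module membership detectable from topology alone).
#'
#' @param n_nodes network size, default 2000.
#' @param attachment_edges edges added per node during
#'   preferential-attachment growth, default 3.
#' @param module_size planted disease-module size, default 100.
#' @param n_seed_lists number of seed gene lists, default 10.
#' @param seed_list_size genes per seed list, default 60.
#' @param seed_overlap_frac fraction of each seed list drawn from the
#'   module (the rest is background), default 0.5.
#' @param n_positives positive-label genes (module members), default 50.
#' @param module_edge_prob probability of adding each missing
#'   module-internal edge, default 0 (module is a bare node set).
#' @param rng_seed integer seed; the whole benchmark is reproducible
#'   from it.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_nodes = 2000L, attachment_edges = 3L,
                             module_size = 100L, n_seed_lists = 10L,
                             seed_list_size = 60L, seed_overlap_frac = 0.5,
                             n_positives = 50L, module_edge_prob = 0,
                             rng_seed = 1L) {
  stopifnot(module_size < n_nodes,
            seed_overlap_frac >= 0, seed_overlap_frac <= 1,
            n_positives <= module_size,
            module_edge_prob >= 0, module_edge_prob <= 1,
            attachment_edges >= 1L, n_seed_lists >= 1L, seed_list_size >= 1L)
  n_module_seeds <- round(seed_overlap_frac * seed_list_size)
  if (n_module_seeds > module_size) {
    stop_data("seed_overlap_frac * seed_list_size exceeds module_size")
  }
  if (seed_list_size - n_module_seeds > n_nodes - module_size) {
    stop_data("background portion of seed lists exceeds available non-module genes")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment_edges = as.integer(attachment_edges),
                 module_size = as.integer(module_size),
                 n_seed_lists = as.integer(n_seed_lists),
                 seed_list_size = as.integer(seed_list_size),
                 seed_overlap_frac = seed_overlap_frac,
                 n_positives = as.integer(n_positives),
                 module_edge_prob = module_edge_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "benchmark_config")
}

#' Generate a planted-module benchmark
#'
#' Builds a connected preferential-attachment network, plants a disease
#' module (a random node set, optionally densified internally per
#' `module_edge_prob`), draws seed lists that take
#' `seed_overlap_frac * seed_list_size` genes from the module and the
#' rest from the background, labels `n_positives` module genes as
#' positives, and sets the exclusion list to the whole module — so
#' sampled negatives are genuine background genes and unlabeled module
#' genes (the analog of weaker curated candidates) are never mislabeled.
#'
#' @param cfg a [benchmark_config()].
#' @return List with elements `network` (connected `gene_network`),
#'   `seed_sets` (named list of [gene_set()]), `positives`, `exclusion`
#'   (gene sets), `module` (character vector of module genes), and
#'   `config`.
#' @export
generate_benchmark <- function(cfg = benchmark_config()) {
  stopifnot(inherits(cfg, "benchmark_config"))
  with_rng(cfg$rng_seed, {
    g <- igraph::sample_pa(cfg$n_nodes, m = cfg$attachment_edges,
                           directed = FALSE)
    nodes <- sprintf("G%05d", seq_len(cfg$n_nodes))
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]],
                        stringsAsFactors = FALSE)
    module <- sample(nodes, cfg$module_size)
    if (cfg$module_edge_prob > 0 && cfg$module_size >= 2L) {
      pairs <- utils::combn(sort(module), 2L)
      add <- stats::runif(ncol(pairs)) < cfg$module_edge_prob
      if (any(add)) {
        edges <- rbind(edges,
                       data.frame(from = pairs[1L, add], to = pairs[2L, add],
                                  stringsAsFactors = FALSE))
      }
    }
    net <- main_component(gene_network(edges, nodes = nodes))
    background <- setdiff(nodes, module)
    n_mod <- round(cfg$seed_overlap_frac * cfg$seed_list_size)
    seed_sets <- lapply(seq_len(cfg$n_seed_lists), function(k) {
      genes <- c(sample(module, n_mod),
                 sample(background, cfg$seed_list_size - n_mod))
      gene_set(sprintf("list%02d", k), sample(genes))
    })
    names(seed_sets) <- vapply(seed_sets, `[[`, character(1L), "name")
    positives <- gene_set("positives", sample(module, cfg$n_positives))
    exclusion <- gene_set("exclusion", module)
    list(network = net, seed_sets = seed_sets, positives = positives,
         exclusion = exclusion, module = module, config = cfg)
  })
}

#' Write benchmark artifacts in the package's standard file formats
#'
#' Emits the edge-list TSV, a GMT of seed lists, plain-text positive and
#' exclusion lists, and a JSON manifest of the generating configuration.
#'
#' @param bench result of [generate_benchmark()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             seeds = file.path(dir, "seed_lists.gmt"),
             positives = file.path(dir, "positives.txt"),
             exclusion = file.path(dir, "exclusion.txt"),
             manifest = file.path(dir, "manifest.json"))
  write_edge_list(bench$network, paths[["network"]])
  write_gene_sets(bench$seed_sets, paths[["seeds"]])
  writeLines(bench$positives$genes, paths[["positives"]])
  writeLines(bench$exclusion$genes, paths[["exclusion"]])
  fp <- network_fingerprint(bench$network)
  jsonlite::write_json(
    list(config = unclass(bench$config), network = fp,
         n_seed_lists = length(bench$seed_sets)),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(paths)
}
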