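#' Propagation settings
#'
#' Configuration for the random-walk-with-restart diffusion
#' `F <- alpha * W %*% F + (1 - alpha) * Y`. `alpha` is the damping
#' parameter: the weight on the network-diffusion term, so `1 - alpha` is
#' the restart (seed) weight. The default 0.8 is the conventional value
#' for propagation-based gene prioritization.
#'
#' @param alpha damping parameter in (0, 1), default 0.8.
#' @param tol convergence tolerance on the maximum absolute score change
#'   between iterations, default 1e-8.
#' @param max_iter iteration cap; exceeding it is a hard error.
#' @param operator_norm `"symmetric"` for `D^-1/2 A D^-1/2` (default; a
#'   symmetric positive-definite solve) or `"row_stochastic"` for `D^-1 A`.
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(alpha = 0.8, tol = 1e-8, max_iter = 1000L,
                               operator_norm = c("symmetric", "row_stochastic")) {
  operator_norm <- match.arg(operator_norm)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(tol), tol > 0, max_iter >= 1L)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 operator_norm = operator_norm),
            class = "propagation_config")
}

#' @export
print.propagation_config <- function(x, ...) {
  cat(sprintf("<propagation_config> alpha=%g tol=%g max_iter=%d operator=%s\n",
              x$alpha, x$tol, x$max_iter, x$operator_norm))
  invisible(x)
}

#' Build the initial seed mass vector
#'
#' Each seed gene present in the network receives mass `1/s`, where `s`
#' is the number of seed genes retained after dropping those absent from
#' the network (dropped genes trigger a warning); all other nodes get 0,
#' so the vector always sums to 1.
#'
#' @param net a `gene_network`.
#' @param seeds a [gene_set()] or character vector of gene identifiers.
#' @return Named numeric vector over `net$nodes`.
#' @export
build_seed_vector <- function(net, seeds) {
  stopifnot(inherits(net, "gene_network"))
  nm <- if (inherits(seeds, "gene_set")) seeds$name else "seed set"
  genes <- if (inherits(seeds, "gene_set")) seeds$genes else unique(as.character(seeds))
  present <- genes[genes %in% net$nodes]
  absent <- setdiff(genes, present)
  if (!length(present)) {
    stop_data("no gene of '", nm, "' is present in the network")
  }
  if (length(absent)) {
    warning(sprintf("'%s': %d of %d seed genes absent from the network and dropped",
                    nm, length(absent), length(genes)), call. = FALSE)
  }
  y <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  y[present] <- 1 / length(present)
  y
}

#' Degree-normalized adjacency operator
#'
#' @param net a connected `gene_network` with no zero-degree node.
#' @param mode `"symmetric"` returns `D^-1/2 A D^-1/2`;
#'   `"row_stochastic"` returns `D^-1 A`.
#' @return Sparse node-by-node operator matrix in network node order.
#' @export
normalize_adjacency <- function(net, mode = c("symmetric", "row_stochastic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "gene_network"))
  A <- net$adjacency
  if (!net$weighted) A@x <- rep(1, length(A@x))
  d <- Matrix::rowSums(A)
  if (any(d == 0)) {
    stop_data("network has zero-degree node(s): ",
              paste(utils::head(net$nodes[d == 0], 5L), collapse = ", "))
  }
  W <- if (mode == "symmetric") {
    s <- Matrix::Diagonal(x = 1 / sqrt(d))
    s %*% A %*% s
  } else {
    Matrix::Diagonal(x = 1 / d) %*% A
  }
  dimnames(W) <- list(net$nodes, net$nodes)
  W
}

score_vector <- function(values, kind) {
  structure(values, kind = kind)
}

#' Propagate seed mass over the network (iterative fixed point)
#'
#' Iterates `F <- alpha * W %*% F + (1 - alpha) * Y` from `F = Y` until
#' the maximum absolute change falls below `cfg$tol`. The fixed point
#' equals the direct solution `(1 - alpha) * solve(I - alpha W, Y)` (see
#' [propagate_direct()]); on a connected network with non-empty seed all
#' raw scores are strictly positive. Because the spectral radius of `W`
#' is at most 1, the residual contracts at least geometrically with
#' factor `alpha`.
#'
#' @param net a connected `gene_network`.
#' @param seed seed vector from [build_seed_vector()] (named numeric over
#'   `net$nodes`).
#' @param cfg a [propagation_config()].
#' @return Named numeric score vector (`kind` attribute `"raw"`), with
#'   attributes `iterations` and `residuals` (per-iteration max absolute
#'   change).
#' @export
propagate <- function(net, seed, cfg = propagation_config()) {
  stopifnot(inherits(net, "gene_network"), inherits(cfg, "propagation_config"))
  seed <- check_seed(net, seed)
  W <- normalize_adjacency(net, cfg$operator_norm)
  y <- unname(seed)
  f <- y
  resid <- numeric(0L)
  for (it in seq_len(cfg$max_iter)) {
    f_new <- as.numeric(cfg$alpha * (W %*% f)) + (1 - cfg$alpha) * y
    r <- max(abs(f_new - f))
    resid[it] <- r
    f <- f_new
    if (r < cfg$tol) {
      out <- score_vector(stats::setNames(f, net$nodes), "raw")
      attr(out, "iterations") <- it
      attr(out, "residuals") <- resid
      return(out)
    }
  }
  stop_data(sprintf("propagation did not converge in %d iterations (last residual %.3g, tol %.3g)",
                    cfg$max_iter, resid[length(resid)], cfg$tol))
}

check_seed <- function(net, seed) {
  if (is.null(names(seed)) || length(seed) != length(net$nodes) ||
      !identical(names(seed), net$nodes)) {
    stop_data("seed vector must be named by and aligned to the network nodes; use build_seed_vector()")
  }
  if (any(seed < 0) || sum(seed) <= 0) stop_data("seed vector must be nonnegative with positive total mass")
  seed
}

#' Propagate by direct linear solve
#'
#' Exact solution `(1 - alpha) * solve(I - alpha W, Y)` of the
#' random-walk-with-restart fixed point, via a sparse LU factorization.
#' Serves as the reference implementation the iterative solver is tested
#' against; guarded to networks of at most 5,000 nodes.
#'
#' @inheritParams propagate
#' @return Named numeric score vector (`kind` attribute `"raw"`).
#' @export
propagate_direct <- function(net, seed, cfg = propagation_config()) {
  stopifnot(inherits(net, "gene_network"), inherits(cfg, "propagation_config"))
  seed <- check_seed(net, seed)
  n <- length(net$nodes)
  if (n > 5000L) {
    stop_data("propagate_direct is limited to networks of <= 5000 nodes (got ", n, ")")
  }
  W <- normalize_adjacency(net, cfg$operator_norm)
  M <- Matrix::Diagonal(n) - cfg$alpha * W
  f <- as.numeric(Matrix::solve(M, (1 - cfg$alpha) * unname(seed)))
  score_vector(stats::setNames(f, net$nodes), "raw")
}

#' Uniform-seed propagation baseline
#'
#' Propagation score of every node under the uniform seed (`1/n` on each
#' node) with the given configuration. As the damping parameter grows
#' this smoothing approaches a dominant-eigenvector profile of the
#' operator, i.e. an (eigenvector-)centrality-like measure of each node;
#' it is the degree-bias reference used by [normalize_scores()].
#'
#' @inheritParams propagate
#' @return Named numeric baseline score vector, strictly positive on a
#'   connected network.
#' @export
propagation_baseline <- function(net, cfg = propagation_config()) {
  n <- length(net$nodes)
  uniform <- stats::setNames(rep(1 / n, n), net$nodes)
  propagate(net, uniform, cfg)
}

#' Normalize raw propagation scores against degree bias
#'
#' Hub genes accumulate propagation mass regardless of seed identity.
#' This divides each raw score by the node's uniform-seed baseline (see
#' [propagation_baseline()]), an eigenvector-centrality-style correction:
#' a normalized score above 1 means the node received more mass from this
#' seed set than a seed-agnostic walker would deliver.
#'
#' @param raw raw score vector from [propagate()], aligned to `net$nodes`.
#' @param net the network the scores were computed on.
#' @param cfg the [propagation_config()] used for `raw`.
#' @param baseline optional precomputed [propagation_baseline()] result
#'   (reused across seed lists by [build_feature_matrix()]).
#' @return Named numeric score vector (`kind` attribute `"normalized"`).
#' @export
normalize_scores <- function(raw, net, cfg = propagation_config(), baseline = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (is.null(names(raw)) || !identical(names(raw), net$nodes)) {
    stop_data("raw score vector is not aligned to the network node order")
  }
  if (is.null(baseline)) baseline <- propagation_baseline(net, cfg)
  if (!identical(names(baseline), net$nodes)) {
    stop_data("baseline is not aligned to the network node order")
  }
  if (any(baseline <= 0)) stop_data("baseline has non-positive entries; is the network connected?")
  score_vector(stats::setNames(as.numeric(raw) / as.numeric(baseline), net$nodes),
               "normalized")
}

#' Write scores as a two-column TSV
#'
#' Columns `gene` and `score`, sorted by descending score.
#'
#' @param scores named numeric score vector.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  ord <- order(-as.numeric(scores), names(scores))
  df <- data.frame(gene = names(scores)[ord],
                   score = sprintf("%.15g", as.numeric(scores)[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a two-column score TSV written by [write_scores()]
#'
#' @param path input path.
#' @return Named numeric vector.
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  stats::setNames(df[[2L]], df[[1L]])
}
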