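#' Build the genes-by-seed-sets feature matrix
#'
#' For each seed list, mass is propagated over the network and the raw
#' scores are degree-bias-normalized against the shared uniform-seed
#' baseline; column k of the result holds the normalized scores of seed
#' set k. Rows follow the network node order, columns the input order of
#' the seed sets. These per-list scores are the classifier's features:
#' one evidence layer per column.
#'
#' @param net a connected `gene_network` (run [main_component()] first).
#' @param seed_sets named list of [gene_set()] objects with unique names.
#' @param cfg a [propagation_config()].
#' @return An object of class `feature_matrix`: list with `genes`,
#'   `set_names`, `values` (genes x K numeric matrix with dimnames) and
#'   `provenance` (propagation settings plus [network_fingerprint()]).
#' @export
build_feature_matrix <- function(net, seed_sets, cfg = propagation_config()) {
  stopifnot(inherits(net, "gene_network"), length(seed_sets) >= 1L)
  if (inherits(seed_sets, "gene_set")) seed_sets <- list(seed_sets)
  set_names <- vapply(seed_sets, function(s) {
    if (!inherits(s, "gene_set")) stop_data("seed_sets must contain gene_set objects")
    s$name
  }, character(1L))
  if (anyDuplicated(set_names)) {
    stop_data("duplicate seed set name(s): ",
              paste(unique(set_names[duplicated(set_names)]), collapse = ", "))
  }
  baseline <- propagation_baseline(net, cfg)
  values <- vapply(seed_sets, function(s) {
    y <- build_seed_vector(net, s)
    as.numeric(normalize_scores(propagate(net, y, cfg), net, cfg, baseline = baseline))
  }, numeric(length(net$nodes)))
  dimnames(values) <- list(net$nodes, set_names)
  fp <- network_fingerprint(net)
  structure(
    list(genes = net$nodes, set_names = unname(set_names), values = values,
         provenance = list(alpha = cfg$alpha, tol = cfg$tol,
                           operator_norm = cfg$operator_norm,
                           n_nodes = fp$n_nodes, n_edges = fp$n_edges,
                           hash = fp$hash)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d genes x %d seed sets (alpha=%g, %s)\n",
              length(x$genes), length(x$set_names),
              x$provenance$alpha, x$provenance$operator_norm))
  invisible(x)
}

#' Write a feature matrix as TSV with a provenance header
#'
#' `#`-prefixed header lines record the propagation settings and the
#' network fingerprint; values are written with 15 significant digits so
#' a read/write round trip is lossless to at least 12.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  p <- fm$provenance
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# propforest feature matrix",
    sprintf("# alpha=%.15g tol=%.15g operator_norm=%s", p$alpha, p$tol, p$operator_norm),
    sprintf("# network n_nodes=%d n_edges=%d hash=%s", p$n_nodes, p$n_edges, p$hash),
    paste(c("gene", fm$set_names), collapse = "\t")
  ), con)
  body <- apply(fm$values, 1L, function(v) paste(sprintf("%.15g", v), collapse = "\t"))
  writeLines(paste(fm$genes, body, sep = "\t"), con)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path input path.
#' @param net optional `gene_network`; when supplied, a provenance
#'   mismatch (different fingerprint) raises a warning.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, net = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  body <- lines[!hdr]
  if (length(body) < 2L) stop_data("feature matrix file has no data rows: ", path)
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (cols[1L] != "gene" || length(cols) < 2L) {
    stop_data("malformed feature matrix header in ", path)
  }
  set_names <- cols[-1L]
  fields <- strsplit(body[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    stop_data(sprintf("row %d of %s has %d columns, expected %d",
                      which(nf != length(cols))[1L], path,
                      nf[nf != length(cols)][1L], length(cols)))
  }
  genes <- vapply(fields, `[[`, character(1L), 1L)
  values <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                     numeric(length(set_names))))
  if (length(set_names) == 1L) values <- matrix(values, ncol = 1L)
  if (anyNA(values)) stop_data("non-numeric feature value in ", path)
  dimnames(values) <- list(genes, set_names)
  prov <- parse_provenance(meta)
  fm <- structure(list(genes = genes, set_names = set_names, values = values,
                       provenance = prov),
                  class = "feature_matrix")
  if (!is.null(net)) {
    fp <- network_fingerprint(net)
    if (!identical(fp$hash, prov$hash %||% NA_character_)) {
      warning("feature matrix provenance does not match the supplied network",
              call. = FALSE)
    }
  }
  fm
}

parse_provenance <- function(meta) {
  kv <- unlist(regmatches(meta, gregexpr("[A-Za-z_]+=[^ ]+", meta)))
  if (!length(kv)) return(list())
  parts <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(parts, `[[`, character(1L), 2L),
                          vapply(parts, `[[`, character(1L), 1L))
  chr <- function(k) if (k %in% names(vals)) vals[[k]] else NULL
  num <- function(k) if (k %in% names(vals)) as.numeric(vals[[k]]) else NULL
  list(alpha = num("alpha"), tol = num("tol"),
       operator_norm = chr("operator_norm"),
       n_nodes = num("n_nodes"), n_edges = num("n_edges"),
       hash = chr("hash"))
}
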