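#' Construct a gene interaction network
#'
#' Builds the canonical undirected network object used throughout the
#' package: a set of gene identifiers (opaque, case-sensitive strings), a
#' canonicalized edge table, and a symmetric sparse adjacency matrix.
#' Self-loops are dropped and duplicate edges (including reversed
#' duplicates) are collapsed; the first weight seen for an edge wins.
#'
#' @param edges two-column character matrix or data frame of endpoints
#'   (an optional third column holds numeric weights).
#' @param nodes optional character vector of node identifiers; defaults to
#'   the sorted set of edge endpoints. Extra isolated nodes are allowed.
#' @param weights optional numeric edge weights (recycled default 1).
#' @return An object of class `gene_network` with elements `nodes`
#'   (character), `edges` (data frame `from`, `to`, `weight` with
#'   `from < to` lexicographically), `adjacency` (symmetric sparse
#'   [Matrix::dgCMatrix-class] with zero diagonal), and `weighted`
#'   (TRUE when any weight differs from 1).
#' @export
gene_network <- function(edges, nodes = NULL, weights = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_data("edges must have at least two columns")
  if (is.null(weights)) {
    weights <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, nrow(edges))
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_data("edge weights must be finite and nonnegative")
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]; weights <- weights[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  a <- a[first]; b <- b[first]; w <- weights[first]
  ord <- order(a, b)
  edge_df <- data.frame(from = a[ord], to = b[ord], weight = w[ord],
                        stringsAsFactors = FALSE)
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edge_df$from, edge_df$to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop_data("duplicate node identifiers")
    missing <- setdiff(unique(c(edge_df$from, edge_df$to)), nodes)
    if (length(missing)) {
      stop_data("edge endpoints absent from `nodes`: ",
                paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  n <- length(nodes)
  i <- match(edge_df$from, nodes)
  j <- match(edge_df$to, nodes)
  adjacency <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(edge_df$weight, 2L),
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  structure(
    list(nodes = nodes, edges = edge_df, adjacency = adjacency,
         weighted = any(edge_df$weight != 1)),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (x$weighted) " (weighted)" else ""))
  invisible(x)
}

#' Node degrees of a network
#'
#' @param net a `gene_network`.
#' @param weighted use edge weights (default follows the network).
#' @return Named numeric vector of degrees in node order.
#' @export
node_degrees <- function(net, weighted = net$weighted) {
  stopifnot(inherits(net, "gene_network"))
  A <- net$adjacency
  if (!weighted) A@x <- rep(1, length(A@x))
  stats::setNames(Matrix::rowSums(A), net$nodes)
}

#' Read an interaction network from a tab-separated edge list
#'
#' Parses a two- or three-column edge list (`source`, `target`, optional
#' numeric `weight`). Lines starting with `#` and blank lines are skipped.
#' Self-loop rows are dropped with a warning; duplicate and reversed
#' duplicate rows collapse to one undirected edge.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param has_header drop the first non-comment line.
#' @return A validated [gene_network()].
#' @export
read_edge_list <- function(path, delimiter = "\t", has_header = FALSE) {
  if (!file.exists(path)) stop_data("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  rows <- lines[keep]
  if (has_header && length(rows)) {
    rows <- rows[-1L]
    line_no <- line_no[-1L]
  }
  if (!length(rows)) stop_data("no data rows in edge list: ", path)
  fields <- strsplit(rows, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop_data(sprintf("malformed row at line %d of %s: expected 2-3 columns, got %d",
                      line_no[bad[1L]], path, nf[bad[1L]]))
  }
  from <- vapply(fields, `[[`, character(1L), 1L)
  to <- vapply(fields, `[[`, character(1L), 2L)
  weight <- rep(1, length(fields))
  has_w <- nf == 3L
  if (any(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(fields[has_w], `[[`, character(1L), 3L)))
    if (anyNA(w)) {
      bad <- which(has_w)[which(is.na(w))[1L]]
      stop_data(sprintf("non-numeric weight at line %d of %s", line_no[bad], path))
    }
    weight[has_w] <- w
  }
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop row(s) (first at line %d) in %s",
                    sum(loops), line_no[which(loops)[1L]], path), call. = FALSE)
  }
  if (all(loops)) stop_data("no edges remain after removing self-loops: ", path)
  gene_network(data.frame(from = from[!loops], to = to[!loops],
                          weight = weight[!loops], stringsAsFactors = FALSE))
}

#' Write a network as a canonical edge-list TSV
#'
#' Columns `source`, `target` (plus `weight` when the network is weighted),
#' one row per undirected edge with endpoints in lexicographic order.
#'
#' @param net a `gene_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  df <- net$edges
  if (!net$weighted) df$weight <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                vertices = net$nodes)
}

#' Extract the main connected component
#'
#' Returns the induced subgraph on the largest connected component. When
#' several components tie for the largest size, the component containing
#' the lexicographically smallest member node wins, so extraction is
#' deterministic.
#'
#' @param net a `gene_network`.
#' @return A connected `gene_network`.
#' @export
main_component <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  comp <- igraph::components(as_igraph(net))
  if (comp$no == 1L) return(net)
  sizes <- comp$csize
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1L) {
    # smallest node name among members of each maximal component
    reps <- vapply(winners, function(k) min(net$nodes[comp$membership == k]),
                   character(1L))
    winners <- winners[order(reps)[1L]]
  }
  keep_nodes <- net$nodes[comp$membership == winners]
  keep_edges <- net$edges[net$edges$from %in% keep_nodes &
                            net$edges$to %in% keep_nodes, , drop = FALSE]
  gene_network(keep_edges, nodes = sort(keep_nodes))
}

#' Create a named gene set
#'
#' @param name set name (non-empty string).
#' @param genes character vector of gene identifiers; duplicates are
#'   removed keeping first occurrence.
#' @return An object of class `gene_set` with fields `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes) & nzchar(genes)]
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_data("gene set name must be a non-empty string")
  }
  if (!length(genes)) stop_data("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from plain-text or GMT files
#'
#' Plain format holds one gene identifier per line and takes the set name
#' from the file name (extension stripped). GMT holds one set per line:
#' name, description, then members, tab-separated.
#'
#' @param path file path.
#' @param format `"plain"` or `"gmt"`.
#' @return Named list of [gene_set()] objects, in file order.
#' @export
read_gene_sets <- function(path, format = c("plain", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("gene set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "plain") {
    genes <- trimws(lines)
    genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
    nm <- tools::file_path_sans_ext(basename(path))
    if (!length(genes)) stop_data("empty gene set in ", path)
    sets <- list(gene_set(nm, genes))
  } else {
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop_data("empty GMT file: ", path)
    sets <- lapply(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) {
        stop_data("malformed GMT line (need name, description, >=1 member): ",
                  substr(ln, 1L, 60L))
      }
      gene_set(f[1L], f[-(1:2)])
    })
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup)) stop_data("duplicate gene set name(s): ", paste(unique(dup), collapse = ", "))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @param description description column value (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Fingerprint a network for provenance tracking
#'
#' @param net a `gene_network`.
#' @return List with `n_nodes`, `n_edges` and a content `hash` (FNV-1a of
#'   the canonical edge list), stable across runs and platforms.
#' @export
network_fingerprint <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  content <- paste(net$edges$from, net$edges$to, format(net$edges$weight),
                   sep = "|", collapse = ";")
  list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
       hash = fnv1a(content))
}
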