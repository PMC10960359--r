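#' Degree-preserving network randomization
#'
#' Shuffles network topology while conserving every node's degree
#' exactly, by repeated double-edge swaps: two edges (a,b) and (c,d) are
#' replaced by (a,c) and (b,d). Swaps that would create a self-loop or a
#' duplicate edge are rejected and retried. The routine performs
#' `swaps_per_edge * |E|` successful swaps (10 per edge is the
#' conventional burn-in for approximate uniformity over the degree
#' sequence's graph space). This is the negative control for
#' propagation: seed lists keep their identity but lose their network
#' neighborhood.
#'
#' Randomized networks may fragment into several components; callers
#' that need connectivity (propagation) should re-extract the
#' [main_component()] afterwards.
#'
#' If the attempt budget (`max_tries_factor` times the swap target) is
#' exhausted without a single success, graphs with at most 1,000 edges
#' are scanned exhaustively: when no legal swap exists at all (e.g. a
#' triangle) the input topology is returned unchanged with a message;
#' otherwise, and for larger graphs, an error is raised.
#'
#' @param net a `gene_network` with at least 2 edges.
#' @param swaps_per_edge successful swaps to perform per edge, default 10.
#' @param rng_seed integer seed; the same seed gives a bit-identical
#'   result. `NULL` uses the current RNG stream.
#' @param max_tries_factor attempt budget multiplier, default 100.
#' @return A `gene_network` with identical node set and degree sequence.
#' @export
degree_preserving_randomize <- function(net, swaps_per_edge = 10,
                                        rng_seed = NULL,
                                        max_tries_factor = 100L) {
  stopifnot(inherits(net, "gene_network"),
            swaps_per_edge > 0, max_tries_factor >= 1L)
  if (net$weighted) {
    warning("edge weights are discarded by degree-preserving randomization",
            call. = FALSE)
  }
  m <- nrow(net$edges)
  if (m < 2L) stop_data("need at least 2 edges to randomize")
  target <- as.integer(ceiling(swaps_per_edge * m))
  max_tries <- max_tries_factor * target

  ec <- cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))
  with_rng(rng_seed, {
    res <- run_edge_swaps(ec, target, max_tries)
  })
  if (res$done == 0L && !res$any_possible) {
    message("graph is fully constrained: no legal double-edge swap exists; returning input topology")
  }
  gene_network(data.frame(from = net$nodes[pmin(res$edges[, 1L], res$edges[, 2L])],
                          to = net$nodes[pmax(res$edges[, 1L], res$edges[, 2L])],
                          stringsAsFactors = FALSE),
               nodes = net$nodes)
}

# Core swap loop on an integer edge matrix. Edge existence is tracked in a
# hashed environment keyed "min_max". Returns the final edge matrix, the
# number of successful swaps, and (when zero) whether any swap was possible.
run_edge_swaps <- function(ec, target, max_tries) {
  m <- nrow(ec)
  seen <- new.env(hash = TRUE, size = 2L * m)
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  for (k in seq_len(m)) assign(ekey(ec[k, 1L], ec[k, 2L]), TRUE, envir = seen)

  done <- 0L
  tries_since_success <- 0L
  while (done < target) {
    if (tries_since_success >= max_tries) {
      if (done == 0L) {
        if (m <= 1000L && !any_legal_swap(ec, seen, ekey)) {
          return(list(edges = ec, done = 0L, any_possible = FALSE))
        }
        stop_data("no successful double-edge swap within ", max_tries,
                  " attempts; graph may be pathological")
      }
      stop_data(sprintf("stalled after %d of %d swaps (%d fruitless attempts)",
                        done, target, max_tries))
    }
    idx <- sample.int(m, 2L)
    a <- ec[idx[1L], 1L]; b <- ec[idx[1L], 2L]
    c <- ec[idx[2L], 1L]; d <- ec[idx[2L], 2L]
    # random orientation of the second edge so both rewirings are reachable
    if (stats::runif(1L) < 0.5) { tmp <- c; c <- d; d <- tmp }
    tries_since_success <- tries_since_success + 1L
    if (a == c || a == d || b == c || b == d) next
    new1 <- ekey(a, c); new2 <- ekey(b, d)
    if (new1 == new2 || exists(new1, envir = seen, inherits = FALSE) ||
        exists(new2, envir = seen, inherits = FALSE)) next
    rm(list = c(ekey(a, b), ekey(c, d)), envir = seen)
    assign(new1, TRUE, envir = seen)
    assign(new2, TRUE, envir = seen)
    ec[idx[1L], ] <- c(a, c)
    ec[idx[2L], ] <- c(b, d)
    done <- done + 1L
    tries_since_success <- 0L
  }
  list(edges = ec, done = done, any_possible = TRUE)
}

# Exhaustive scan: is any legal double-edge swap available? O(m^2).
any_legal_swap <- function(ec, seen, ekey) {
  m <- nrow(ec)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- ec[i, 1L]; b <- ec[i, 2L]
      for (ori in 1:2) {
        c <- ec[j, ori]; d <- ec[j, 3L - ori]
        if (a == c || a == d || b == c || b == d) next
        n1 <- ekey(a, c); n2 <- ekey(b, d)
        if (n1 != n2 && !exists(n1, envir = seen, inherits = FALSE) &&
            !exists(n2, envir = seen, inherits = FALSE)) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}
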