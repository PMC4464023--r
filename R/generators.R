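#' Erdos-Renyi random network matched to a reference edge count
#'
#' Generates \eqn{G(N, p)} with \eqn{p = m / \binom{N}{2}}, so that the
#' expected number of edges equals `m`; the realized edge count varies
#' between seeds. This is the random control associated to a natural
#' interactome of `N` proteins and `m` interactions.
#'
#' @param N Number of nodes (>= 2).
#' @param m Desired (expected) number of edges, `0 <= m <= N(N-1)/2`.
#' @param seed Optional integer seed; the same seed always yields the same
#'   graph.
#' @return An undirected `igraph` graph with vertex names `n1..nN`.
#' @examples
#' g <- erdos_renyi_network(100, 250, seed = 1)
#' igraph::ecount(g)
#' @export
erdos_renyi_network <- function(N, m, seed = NULL) {
  stopifnot(N >= 2)
  npairs <- N * (N - 1) / 2
  if (m < 0 || m > npairs) {
    stop("m must be between 0 and N(N-1)/2 = ", npairs)
  }
  p <- m / npairs
  g <- with_rng_seed(seed, igraph::sample_gnp(N, p))
  igraph::V(g)$name <- paste0("n", seq_len(N))
  g
}

#' Degree sequence of a network
#'
#' Per-node degree list (loop edges count 2, igraph's convention); the sum
#' equals twice the edge count for loop-free graphs.
#'
#' @param network An `igraph` graph.
#' @return Integer vector of degrees, named if the graph has vertex names.
#' @export
degree_sequence_of <- function(network) {
  igraph::degree(network)
}

#' Random network with prescribed degrees and tunable transitivity
#'
#' Growth process after Volz: nodes carry target degrees ("stubs"); the
#' network grows from a random seed node. Each time a node is current, every
#' node at graph distance 2 with free stubs is a candidate triad closure and
#' is linked with probability `target_transitivity`; if the current node
#' still has free stubs, a new node is drawn into the network at random and
#' attached. Growth continues until every node has at least one neighbour.
#' Stubs left free at the end are resolved by uniform random stub matching
#' that skips self-loops and duplicate edges; unmatchable residual stubs are
#' dropped (count reported via `message`).
#'
#' The closure probability equals the target transitivity itself, so the
#' realized transitivity is a monotone, but not identity, function of the
#' target; always measure the realized value (e.g. with
#' [topology_report()]) for downstream analyses.
#'
#' @param degrees Integer vector of target degrees, one per node (at least
#'   one positive entry). If `n` is given and differs from
#'   `length(degrees)`, the degree list is resampled with replacement to
#'   length `n`.
#' @param target_transitivity Closure probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param n Optional node count overriding `length(degrees)`.
#' @param quiet Suppress the dropped-stub message.
#' @return An undirected simple `igraph` graph with vertex names `n1..nN`.
#' @examples
#' g <- volz_network(rep(3, 60), target_transitivity = 0.8, seed = 1)
#' igraph::transitivity(g)
#' @export
volz_network <- function(degrees, target_transitivity, seed = NULL,
                         n = NULL, quiet = FALSE) {
  stopifnot(target_transitivity >= 0, target_transitivity <= 1)
  degrees <- as.integer(degrees)
  if (any(degrees < 0)) stop("degrees must be non-negative")
  if (all(degrees == 0)) stop("degree sequence is all zero")
  with_rng_seed(seed, {
    if (!is.null(n) && n != length(degrees)) {
      degrees <- sample(degrees, n, replace = TRUE)
      if (all(degrees == 0)) degrees[sample.int(n, 1)] <- 1L
    }
    N <- length(degrees)
    free <- degrees
    adj <- vector("list", N)          # neighbour lists
    in_net <- rep(FALSE, N)
    edges <- integer(0)               # flat pairs
    add_edge <- function(u, v) {
      adj[[u]] <<- c(adj[[u]], v); adj[[v]] <<- c(adj[[v]], u)
      free[u] <<- free[u] - 1L; free[v] <<- free[v] - 1L
      in_net[u] <<- TRUE; in_net[v] <<- TRUE
      edges <<- c(edges, u, v)
    }
    out <- which(degrees > 0)         # nodes not yet in the network
    v0 <- out[sample.int(length(out), 1)]
    out <- setdiff(out, v0)
    in_net[v0] <- TRUE
    queue <- v0
    while (length(out) > 0) {
      if (length(queue) == 0) {       # seed a fresh component
        v <- out[sample.int(length(out), 1)]
        out <- setdiff(out, v)
        in_net[v] <- TRUE
        queue <- v
        next
      }
      vi <- queue[1]; queue <- queue[-1]
      if (free[vi] > 0 && target_transitivity > 0) {
        nb1 <- adj[[vi]]
        cand <- setdiff(unique(unlist(adj[nb1])), c(vi, nb1))
        cand <- cand[free[cand] > 0]
        if (length(cand) > 1) cand <- sample(cand)
        for (u in cand) {
          if (free[vi] == 0) break
          if (stats::runif(1) < target_transitivity) add_edge(vi, u)
        }
      }
      if (free[vi] > 0 && length(out) > 0) {
        u <- out[sample.int(length(out), 1)]
        out <- setdiff(out, u)
        add_edge(vi, u)
        queue <- c(queue, u)
        if (free[vi] > 0) queue <- c(queue, vi)
      }
    }
    # resolve leftover stubs by uniform stub matching, skipping self/duplicate
    stubs <- rep.int(seq_len(N), pmax(free, 0L))
    if (length(stubs) > 1) {
      stubs <- sample(stubs)
      have <- new.env(hash = TRUE)
      if (length(edges)) {
        ek <- paste(pmin(edges[c(TRUE, FALSE)], edges[c(FALSE, TRUE)]),
                    pmax(edges[c(TRUE, FALSE)], edges[c(FALSE, TRUE)]))
        for (k in ek) assign(k, TRUE, envir = have)
      }
      dropped <- 0L
      while (length(stubs) > 1) {
        u <- stubs[1]
        rest <- which(stubs[-1] != u) + 1L
        if (length(rest) == 0) { dropped <- dropped + length(stubs); break }
        ok <- FALSE
        for (j in rest[sample.int(length(rest), min(length(rest), 20L))]) {
          v <- stubs[j]
          k <- paste(min(u, v), max(u, v))
          if (!exists(k, envir = have, inherits = FALSE)) {
            assign(k, TRUE, envir = have)
            edges <- c(edges, u, v)
            stubs <- stubs[-c(1L, j)]
            ok <- TRUE
            break
          }
        }
        if (!ok) { stubs <- stubs[-1L]; dropped <- dropped + 1L }
      }
      dropped <- dropped + length(stubs)
      if (dropped > 0 && !quiet) {
        message("volz_network: dropped ", dropped, " unmatchable stub(s)")
      }
    }
    g <- igraph::make_empty_graph(N, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- paste0("n", seq_len(N))
    g
  })
}

# Evaluate expr under a temporary RNG seed (NULL = use current RNG stream).
# Relies on lazy evaluation: the promise runs in the caller's frame.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
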