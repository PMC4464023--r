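# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive O(N^3) enumeration and base R only.

# adjacency matrix of an igraph graph (loops dropped)
adj_matrix_of <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g)))
  A[A > 1] <- 1
  A
}

# global transitivity by triple counting
oracle_transitivity <- function(g) {
  A <- adj_matrix_of(g)
  n <- nrow(A)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      e <- A[i, j] + A[i, k] + A[j, k]
      if (e == 3) triangles <- triangles + 1
      if (e >= 2) triples <- triples + (if (e == 3) 3 else 1)
    }
  }
  if (triples == 0) return(NaN)
  3 * triangles / triples
}

# Watts-Strogatz average clustering; degree < 2 counts 0
oracle_acc <- function(g) {
  A <- adj_matrix_of(g)
  n <- nrow(A)
  lc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) { lc[i] <- 0; next }
    links <- sum(A[nb, nb]) / 2
    lc[i] <- 2 * links / (k * (k - 1))
  }
  mean(lc)
}

# all-pairs shortest paths by Floyd-Warshall over the largest component
oracle_apl_diameter <- function(g) {
  A <- adj_matrix_of(g)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  # largest component = largest set of mutually reachable nodes
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(D[i, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  d <- D[big, big, drop = FALSE]
  vals <- d[upper.tri(d)]
  list(apl = mean(vals), diameter = max(vals))
}

# random connected-ish small graph for property tests
random_small_graph <- function(n, p = 0.35) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# exhaustive optimal assignment: max mean score over all matchings of the
# smaller side into the larger (permutation enumeration, k <= 6)
oracle_optimal_assignment <- function(M) {
  n <- nrow(M); m <- ncol(M)
  transposed <- n > m
  if (transposed) { M <- t(M); n <- nrow(M); m <- ncol(M) }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (pp in perms(cols)) {
      s <- sum(M[cbind(seq_len(n), pp)])
      if (s > best) best <- s
    }
  }
  best / n
}

# random complex compositions over a small species alphabet
random_cell <- function(n_complexes, alphabet = LETTERS[1:8], max_size = 4) {
  lapply(seq_len(n_complexes), function(i) {
    sample(alphabet, sample(1:max_size, 1))
  })
}
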