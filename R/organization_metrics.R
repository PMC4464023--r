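#' Similarity Index between two complex compositions
#'
#' For complexes with species sets \eqn{C_1} and \eqn{C_2},
#' \deqn{S.I.(C_1, C_2) = \frac{|C_1 \cap C_2|^2}{|C_1 \Delta C_2| + 1}}
#' where \eqn{\Delta} is the symmetric difference. Squaring the
#' intersection weights large shared cores more heavily, so two identical
#' complexes of size k score \eqn{k^2} while disjoint complexes score 0.
#'
#' @param c1,c2 Non-empty vectors of species identifiers (any atomic type);
#'   duplicates within a vector are ignored (a composition is a set).
#' @return A non-negative real; symmetric in its arguments.
#' @examples
#' similarity_index(c("A", "B", "C"), c("B", "C", "D"))  # 4/3
#' @export
similarity_index <- function(c1, c2) {
  if (length(c1) == 0 || length(c2) == 0) stop("complex composition is empty")
  c1 <- unique(c1); c2 <- unique(c2)
  i <- length(intersect(c1, c2))
  sdiff <- length(c1) + length(c2) - 2 * i
  i^2 / (sdiff + 1)
}

#' Pairwise Similarity Index matrix between two complex lists
#'
#' @param cell_a,cell_b Lists of complex compositions (vectors of species
#'   identifiers). Defaults to a square self-comparison of `cell_a`.
#' @return A `length(cell_a)` x `length(cell_b)` numeric matrix of S.I.
#'   values.
#' @export
similarity_matrix <- function(cell_a, cell_b = cell_a) {
  if (length(cell_a) == 0 || length(cell_b) == 0) {
    return(matrix(numeric(0), length(cell_a), length(cell_b)))
  }
  uni <- unique(unlist(c(cell_a, cell_b), use.names = FALSE))
  ia <- lapply(cell_a, function(x) sort(match(unique(x), uni)))
  ib <- lapply(cell_b, function(x) sort(match(unique(x), uni)))
  cpp_similarity_matrix(ia, ib)
}

# Canonical complex ordering: descending size, ties by lexicographic
# species-name signature. Makes the order-dependent SSI deterministic.
canonical_complex_order <- function(cell) {
  if (length(cell) == 0) return(integer(0))
  sizes <- vapply(cell, function(x) length(unique(x)), 1L)
  sig <- vapply(cell, function(x) paste(sort(as.character(unique(x))),
                                        collapse = "\r"), "")
  order(-sizes, sig)
}

#' Self-Similarity Index of a pseudocell
#'
#' Quantifies how repetitive the complex repertoire of one pseudocell is:
#' \deqn{SSI(C) = \frac{1}{n}\sum_{i=1}^{n-1} \max_{j > i} S.I.(C_i, C_j)}
#' over the list \eqn{C = \{C_1 \ldots C_n\}} of complex compositions. A
#' cell assembling many copies of a few complex types has high SSI; a cell
#' whose complexes are all different scores near 0.
#'
#' The literal formula depends on the list order through `j > i`; by
#' default complexes are first put in a canonical order (descending size,
#' then lexicographic composition) so the value is reproducible. The
#' symmetric variant (`symmetric = TRUE`) takes each complex's best match
#' over *all* other complexes and is order-free.
#'
#' @param cell List of complex compositions. Duplicated compositions are
#'   meaningful and retained (the list is a multiset).
#' @param symmetric Use the order-free variant (default `FALSE`).
#' @param order `"canonical"` (default) or `"given"` to keep the list order
#'   as passed.
#' @return SSI >= 0; cells with fewer than 2 complexes return 0 with a
#'   warning.
#' @examples
#' self_similarity_index(list(c("A", "B"), c("A", "B")))  # 4/2 = 2
#' @export
self_similarity_index <- function(cell, symmetric = FALSE,
                                  order = c("canonical", "given")) {
  order <- match.arg(order)
  n <- length(cell)
  if (n < 2) {
    warning("fewer than 2 complexes; SSI reported as 0")
    return(0)
  }
  if (order == "canonical") cell <- cell[canonical_complex_order(cell)]
  M <- similarity_matrix(cell)
  if (symmetric) {
    diag(M) <- -Inf
    return(sum(apply(M, 1, max)) / n)
  }
  best <- vapply(seq_len(n - 1), function(i) max(M[i, (i + 1):n]), 0)
  sum(best) / n
}

#' Inter-Cells Similarity Index between two pseudocells
#'
#' Greedy maximum-first matching of complexes between two cells: the pair
#' with the largest Similarity Index is matched and removed, repeatedly,
#' until the smaller cell is exhausted; ICSI is the mean of the
#' `min(n, m)` recorded values. Ties are broken by the lowest (row,
#' column) index pair. High ICSI means the two cells assembled similar
#' complex repertoires despite independent histories.
#'
#' @param cell_a,cell_b Non-empty lists of complex compositions.
#' @param detail If `TRUE`, also return the matched index pairs and their
#'   scores.
#' @return The ICSI (a non-negative real), or, with `detail = TRUE`, a list
#'   with elements `icsi`, `pairs` (matrix of matched row/col indices) and
#'   `scores`.
#' @examples
#' a <- list(c("A", "B"), c("C", "D", "E"))
#' inter_cell_similarity_index(a, a)  # (9 + 4) / 2 = 6.5
#' @export
inter_cell_similarity_index <- function(cell_a, cell_b, detail = FALSE) {
  if (length(cell_a) == 0 || length(cell_b) == 0) stop("empty cell")
  M <- similarity_matrix(cell_a, cell_b)
  n <- nrow(M); m <- ncol(M)
  k <- min(n, m)
  scores <- numeric(k)
  pairs <- matrix(0L, k, 2, dimnames = list(NULL, c("row", "col")))
  row_ok <- rep(TRUE, n); col_ok <- rep(TRUE, m)
  for (t in seq_len(k)) {
    sub <- M[row_ok, col_ok, drop = FALSE]
    best <- max(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    ri <- which(row_ok)[hit[1]]; ci <- which(col_ok)[hit[2]]
    scores[t] <- M[ri, ci]
    pairs[t, ] <- c(ri, ci)
    row_ok[ri] <- FALSE; col_ok[ci] <- FALSE
  }
  icsi <- mean(scores)
  if (detail) list(icsi = icsi, pairs = pairs, scores = scores) else icsi
}

#' Read a pseudocell complex list from a snapshot file
#'
#' Parses the plain-text snapshot format written by [write_snapshots()]:
#' comment/header lines start with `#`; every other line is one complex as
#' tab-separated species names. Because each species occurs at most once
#' per complex, single-name lines are monomers.
#'
#' @param path Snapshot file path.
#' @param include_monomers Keep single-species entries (default `FALSE`: a
#'   "complex" is at least two proteins).
#' @return A list of character vectors (complex compositions).
#' @export
read_complex_list <- function(path, include_monomers = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  cell <- strsplit(body, "\t", fixed = TRUE)
  bad <- vapply(cell, function(x) any(!nzchar(x)) || anyDuplicated(x) > 0,
                FALSE)
  if (any(bad)) {
    stop("malformed snapshot ", path, ": bad complex at body line ",
         which(bad)[1])
  }
  if (!include_monomers) cell <- cell[lengths(cell) > 1]
  cell
}

#' SSI time series of a simulation trace
#'
#' Computes the Self-Similarity Index for every recorded snapshot of a
#' [protnet_run()] trace.
#'
#' @param trace A `protnet_trace` object.
#' @param include_monomers Count monomers as complexes (default `FALSE`).
#' @param symmetric Passed to [self_similarity_index()].
#' @return A `data.frame` with columns `step`, `n_complexes`, `ssi`.
#' @export
ssi_timeseries <- function(trace, include_monomers = FALSE, symmetric = FALSE) {
  stopifnot(inherits(trace, "protnet_trace"))
  rows <- lapply(trace$snapshots, function(sn) {
    cell <- sn$compositions
    if (!include_monomers) cell <- cell[lengths(cell) > 1]
    ssi <- if (length(cell) < 2) 0 else
      self_similarity_index(cell, symmetric = symmetric)
    data.frame(step = sn$step, n_complexes = length(cell), ssi = ssi)
  })
  do.call(rbind, rows)
}
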