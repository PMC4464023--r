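#' Read a protein-interaction network from an edge list file
#'
#' Parses a whitespace- or tab-separated edge list into an undirected,
#' unweighted, simple [igraph][igraph::igraph-package] graph. The first two
#' columns are interactor names; an optional third numeric column is an
#' interaction confidence score. Duplicate rows (including reversed
#' duplicates such as `A B` / `B A`) are merged; self-interactions
#' (homodimers) are kept as loop edges. Lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path Path to the edge-list file.
#' @param weight_threshold Optional numeric; rows whose score (third column)
#'   is below this value are dropped before deduplication. Requires the file
#'   to have a third column.
#' @param quiet Logical; if `FALSE` (default) the counts of dropped and
#'   duplicate rows are reported with [message()].
#' @return An undirected `igraph` graph with a `name` vertex attribute.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A B", "B C", "C A"), tf)
#' g <- read_edge_list(tf, quiet = TRUE)
#' igraph::ecount(g)
#' @export
read_edge_list <- function(path, weight_threshold = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- rows[which(nf < 2L)[1L]]
    stop("format error: fewer than 2 columns at line ", bad)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  score <- rep(NA_real_, length(fields))
  has3 <- nf >= 3L
  if (any(has3)) {
    raw <- vapply(fields[has3], `[[`, "", 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- rows[has3][which(is.na(val))[1L]]
      stop("parse error: non-numeric score at line ", bad)
    }
    score[has3] <- val
  }
  n_drop <- 0L
  if (!is.null(weight_threshold)) {
    if (!any(has3)) stop("weight_threshold given but file has no score column")
    sel <- !is.na(score) & score >= weight_threshold
    n_drop <- sum(!sel)
    a <- a[sel]; b <- b[sel]
  }
  # canonical unordered pair, self-loops kept
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (!quiet && (n_drop > 0L || n_dup > 0L)) {
    message(sprintf("read_edge_list: dropped %d row(s) below threshold, merged %d duplicate row(s)",
                    n_drop, n_dup))
  }
  verts <- sort(unique(c(lo, hi)))
  igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE) |>
    (\(g) igraph::permute(g, match(igraph::V(g)$name, verts)))()
}

#' Write a network as a two-column edge list
#'
#' One unordered edge per line, tab-separated vertex names. Reading the file
#' back with [read_edge_list()] recovers the same vertex and edge sets.
#'
#' @param network An undirected `igraph` graph; if it has no `name` vertex
#'   attribute, vertex indices are used as names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(igraph::is_igraph(network))
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(network)))
  el <- igraph::as_edgelist(network, names = FALSE)
  if (nrow(el) == 0L) {
    con <- file(path, "w"); close(con)
    return(invisible(path))
  }
  a <- nm[el[, 1]]; b <- nm[el[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  writeLines(paste(lo, hi, sep = "\t"), path)
  invisible(path)
}

#' Deterministic fixture networks
#'
#' Small named graphs used in tests, demos and desk-scale simulation
#' studies. `clique_chain` and `ring_of_cliques` are clique-rich (high
#' transitivity) fixtures that emulate the modular, cohesive neighbourhoods
#' of natural interactomes; `star` and `path` are low-clustering controls;
#' `figure2_toy` is a 7-protein graph of two overlapping triangles plus a
#' pendant dimer, small enough that its possible complexes can be enumerated
#' by hand.
#'
#' @param kind One of `"figure2_toy"`, `"clique_chain"`, `"star"`,
#'   `"path"`, `"ring_of_cliques"`.
#' @param size Number of cliques (for clique fixtures), leaves (star), or
#'   path edges. Ignored for `figure2_toy`.
#' @param clique_size Nodes per clique for the clique fixtures (default 5).
#' @return An undirected `igraph` graph with character vertex names.
#' @examples
#' g <- make_fixture_network("ring_of_cliques", 4)
#' igraph::transitivity(g)
#' @export
make_fixture_network <- function(kind = c("figure2_toy", "clique_chain", "star",
                                          "path", "ring_of_cliques"),
                                 size = 3, clique_size = 5) {
  kind <- match.arg(kind)
  stopifnot(size >= 1)
  g <- switch(kind,
    figure2_toy = igraph::graph_from_edgelist(cbind(
      c("A", "A", "B", "B", "C", "D", "F"),
      c("B", "C", "C", "D", "D", "E", "G")), directed = FALSE),
    star = igraph::make_star(size + 1L, mode = "undirected", center = 1),
    path = igraph::make_ring(size + 1L, circular = FALSE),
    clique_chain = {
      gs <- lapply(seq_len(size), function(i) igraph::make_full_graph(clique_size))
      g <- Reduce(igraph::disjoint_union, gs)
      if (size > 1) {
        # bridge consecutive cliques through one shared edge endpoint
        br <- cbind((seq_len(size - 1) - 1) * clique_size + clique_size,
                    seq_len(size - 1) * clique_size + 1)
        g <- igraph::add_edges(g, t(br))
      }
      g
    },
    ring_of_cliques = {
      gs <- lapply(seq_len(size), function(i) igraph::make_full_graph(clique_size))
      g <- Reduce(igraph::disjoint_union, gs)
      if (size > 1) {
        nxt <- c(seq_len(size)[-1], 1L)
        br <- cbind((seq_len(size) - 1) * clique_size + clique_size,
                    (nxt - 1) * clique_size + 1)
        br <- br[br[, 1] != br[, 2], , drop = FALSE]
        g <- igraph::add_edges(g, t(unique(br)))
      }
      g
    })
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- paste0("P", seq_len(igraph::vcount(g)))
  }
  igraph::simplify(g, remove.loops = FALSE)
}
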