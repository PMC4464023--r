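#' Global transitivity of a network
#'
#' Three times the number of triangles divided by the number of connected
#' triples (paths of length 2). Loop and multi-edges are ignored.
#'
#' @param network An `igraph` graph with at least 3 nodes.
#' @return Value in `[0, 1]`; `0` with a warning when the graph has no
#'   connected triples.
#' @export
network_transitivity <- function(network) {
  stopifnot(igraph::vcount(network) >= 3)
  tr <- igraph::transitivity(igraph::simplify(network), type = "global")
  if (is.nan(tr)) {
    warning("no connected triples; transitivity reported as 0")
    tr <- 0
  }
  tr
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the local (Watts-Strogatz) clustering
#' coefficient. Nodes of degree < 2, whose local coefficient is undefined,
#' contribute 0 rather than being excluded (the NetworkAnalyzer
#' convention); set `drop_low_degree = TRUE` to average over degree >= 2
#' nodes only.
#'
#' @inheritParams network_transitivity
#' @param drop_low_degree Exclude degree < 2 nodes instead of counting them
#'   as 0.
#' @return Value in `[0, 1]`.
#' @export
average_clustering_coefficient <- function(network, drop_low_degree = FALSE) {
  stopifnot(igraph::vcount(network) >= 3)
  lc <- igraph::transitivity(igraph::simplify(network), type = "local")
  if (drop_low_degree) lc <- lc[!is.na(lc)] else lc[is.na(lc)] <- 0
  if (length(lc) == 0) return(0)
  mean(lc)
}

#' Average path length and diameter
#'
#' Shortest-path statistics over the largest connected component:
#' `average_path_length` is the mean shortest-path length over all ordered
#' reachable pairs, `network_diameter` the maximum. Restricting to the
#' largest component matches how path statistics are conventionally
#' reported for interactomes, whose random controls typically contain
#' isolated nodes.
#'
#' @param network An `igraph` graph with at least one edge.
#' @return `average_path_length`: a real >= 1; `network_diameter`: an
#'   integer >= 1.
#' @export
average_path_length <- function(network) {
  igraph::mean_distance(largest_component(network), directed = FALSE)
}

#' @rdname average_path_length
#' @export
network_diameter <- function(network) {
  as.integer(igraph::diameter(largest_component(network), directed = FALSE,
                              unconnected = FALSE))
}

largest_component <- function(network) {
  if (igraph::ecount(network) == 0) stop("network has no edges")
  comp <- igraph::components(network)
  igraph::induced_subgraph(network, which(comp$membership == which.max(comp$csize)))
}

#' Scale-free fitting index (SFFI)
#'
#' Goodness of fit (R-squared) of the ordinary least-squares line through
#' the degree distribution on log-log axes: points are
#' `(log10 k, log10 P(k))` over the degrees `k >= 1` that occur in the
#' network, with `P(k)` the fraction of nodes of degree `k` (no binning).
#' A value near 1 indicates a power-law-like degree distribution.
#'
#' @param x An `igraph` graph, or directly an integer vector of node
#'   degrees.
#' @return R-squared of the log-log fit, in `[0, 1]`.
#' @export
scale_free_fitting_index <- function(x) {
  deg <- if (igraph::is_igraph(x)) igraph::degree(x) else as.integer(x)
  tab <- table(deg[deg > 0])
  if (length(tab) < 3) {
    stop("scale-free fitting index undefined: fewer than 3 distinct degrees")
  }
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(deg)
  y <- log10(pk)
  fit <- stats::lm(y ~ log10(k))
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Network modularity
#'
#' Newman modularity Q of the partition found by greedy agglomerative
#' modularity maximization (fast-greedy community detection). Loop edges
#' are removed first.
#'
#' @inheritParams network_transitivity
#' @return Modularity Q of the detected partition.
#' @export
network_modularity <- function(network) {
  g <- igraph::simplify(network)
  cl <- igraph::cluster_fast_greedy(g)
  igraph::modularity(cl)
}

#' Topological metric panel of a network
#'
#' Assembles the metric vector used to characterize simulation input
#' networks: node and edge counts, scale-free fitting index (SFFI),
#' average path length (APL) and diameter of the largest component,
#' average clustering coefficient (ACC), global transitivity and
#' modularity. Metrics whose preconditions fail (e.g. SFFI on a regular
#' graph) are reported as `NA`.
#'
#' @param network An `igraph` graph.
#' @param label Optional character label stored in the report.
#' @return A one-row `data.frame` of class `"topology_report"` with columns
#'   `label`, `n_nodes`, `n_edges`, `sffi`, `apl`, `diameter`, `acc`,
#'   `transitivity`, `modularity`.
#' @examples
#' topology_report(make_fixture_network("ring_of_cliques", 4), "ring")
#' @export
topology_report <- function(network, label = NA_character_) {
  try_na <- function(expr) tryCatch(suppressWarnings(expr),
                                    error = function(e) NA_real_)
  out <- data.frame(
    label = label,
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    sffi = try_na(scale_free_fitting_index(network)),
    apl = try_na(average_path_length(network)),
    diameter = try_na(as.numeric(network_diameter(network))),
    acc = try_na(average_clustering_coefficient(network)),
    transitivity = try_na(network_transitivity(network)),
    modularity = try_na(network_modularity(network)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology_report", "data.frame")
  out
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology report", if (!is.na(x$label)) paste0("(", x$label, ")"),
      "\n")
  cat(sprintf("  nodes %d, edges %d\n", x$n_nodes, x$n_edges))
  for (f in c("sffi", "apl", "diameter", "acc", "transitivity", "modularity")) {
    cat(sprintf("  %-12s %s\n", toupper(f),
                ifelse(is.na(x[[f]]), "NA", format(x[[f]], digits = 4))))
  }
  invisible(x)
}
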