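# Derive reproducible per-replicate seeds from one master seed.
derive_seeds <- function(master, n) {
  with_rng_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

#' SSI evolution: structured network versus random control
#'
#' For each replicate, runs one pseudocell under the rules of `network` and
#' one under a matched Erdos-Renyi control (same node count, expected edge
#' count equal to the network's edge count), recording the SSI time
#' series. This is the experiment showing that networks with natural-like
#' topology keep self-organizing after random controls plateau.
#'
#' @param network Rule network (`igraph`).
#' @param config A [protnet_config()]; its `seed` is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param replicates Pseudocells per condition.
#' @param seed Master seed; all replicate seeds and control networks derive
#'   from it deterministically.
#' @param control One of `"er"` (generate a matched Erdos-Renyi control
#'   per replicate family) or `"none"`.
#' @return A `data.frame` with columns `condition` (`"network"` /
#'   `"random"`), `replicate`, `step`, `n_complexes`, `ssi`; the
#'   configuration is attached as attribute `"config"`.
#' @export
ssi_evolution_study <- function(network, config = protnet_profile("desk"),
                                replicates = 10, seed = 1,
                                control = c("er", "none")) {
  control <- match.arg(control)
  seeds <- derive_seeds(seed, replicates + 1L)
  nets <- list(network = network)
  if (control == "er") {
    nets$random <- erdos_renyi_network(igraph::vcount(network),
                                       igraph::ecount(network),
                                       seed = seeds[replicates + 1L])
  }
  rows <- list()
  for (cond in names(nets)) {
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$seed <- seeds[r] + (match(cond, names(nets)) - 1L)
      tr <- protnet_run(nets[[cond]], cfg)
      ts <- ssi_timeseries(tr)
      ts$condition <- cond
      ts$replicate <- r
      rows[[length(rows) + 1L]] <- ts
    }
  }
  out <- do.call(rbind, rows)[, c("condition", "replicate", "step",
                                  "n_complexes", "ssi")]
  attr(out, "config") <- config
  out
}

#' ICSI robustness: similarity of independently evolved pseudocells
#'
#' Runs `replicates` pseudocells per condition from different random
#' initial distributions and computes the Inter-Cells Similarity Index
#' between every pair of final snapshots. High pairwise ICSI means the
#' network funnels independent initial conditions toward the same complex
#' repertoire.
#'
#' @inheritParams ssi_evolution_study
#' @param include_monomers Count monomers as complexes (default `FALSE`).
#' @return A long `data.frame` with columns `condition`, `rep_a`, `rep_b`,
#'   `icsi` (one row per unordered replicate pair); configuration attached
#'   as attribute `"config"`.
#' @export
icsi_robustness_study <- function(network, config = protnet_profile("desk"),
                                  replicates = 10, seed = 1,
                                  control = c("er", "none"),
                                  include_monomers = FALSE) {
  control <- match.arg(control)
  seeds <- derive_seeds(seed, replicates + 1L)
  nets <- list(network = network)
  if (control == "er") {
    nets$random <- erdos_renyi_network(igraph::vcount(network),
                                       igraph::ecount(network),
                                       seed = seeds[replicates + 1L])
  }
  rows <- list()
  for (cond in names(nets)) {
    cells <- lapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$seed <- seeds[r] + 7919L * (match(cond, names(nets)) - 1L)
      tr <- protnet_run(nets[[cond]], cfg)
      sn <- tr$snapshots[[length(tr$snapshots)]]
      cell <- sn$compositions
      if (!include_monomers) cell <- cell[lengths(cell) > 1]
      lapply(cell, function(s) tr$species[s])
    })
    for (a in seq_len(replicates - 1)) {
      for (b in seq((a + 1), replicates)) {
        icsi <- if (length(cells[[a]]) == 0 || length(cells[[b]]) == 0) 0
                else inter_cell_similarity_index(cells[[a]], cells[[b]])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, rep_a = a, rep_b = b, icsi = icsi,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' Topology-to-SSI study over tunable-transitivity network families
#'
#' For each family (a source of degree sequences), each target transitivity
#' on `grid` and each replicate: generate a Volz network, measure its
#' realized topology with [topology_report()], simulate a pseudocell and
#' record the equilibrium SSI (mean over the final 10% of snapshots). The
#' realized -- not target -- metrics are the predictors for
#' [fit_ssi_model()].
#'
#' @param families Named list; each element is either an `igraph` network
#'   (its degree sequence is the family's) or an integer degree vector.
#' @param grid Target transitivity values (default `seq(0, 1, 0.1)`).
#' @param config A [protnet_config()] for the pseudocell runs.
#' @param replicates Networks per (family, transitivity) cell.
#' @param seed Master seed.
#' @return A `data.frame` of one row per simulated network: `family`,
#'   `target_transitivity`, `replicate`, the [topology_report()] columns,
#'   and `ssi` (equilibrium SSI); configuration attached as attribute
#'   `"config"`.
#' @export
topology_ssi_study <- function(families, grid = seq(0, 1, 0.1),
                               config = protnet_profile("desk"),
                               replicates = 1, seed = 1) {
  stopifnot(length(families) > 0, !is.null(names(families)),
            all(grid >= 0), all(grid <= 1), replicates >= 1)
  n_runs <- length(families) * length(grid) * replicates
  seeds <- derive_seeds(seed, 2L * n_runs)
  rows <- list()
  k <- 0L
  for (fam in names(families)) {
    src <- families[[fam]]
    degs <- if (igraph::is_igraph(src)) as.integer(igraph::degree(src))
            else as.integer(src)
    for (tt in grid) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        g <- volz_network(degs, tt, seed = seeds[k], quiet = TRUE)
        rep_ <- topology_report(g, label = fam)
        cfg <- config
        cfg$seed <- seeds[n_runs + k]
        tr <- protnet_run(g, cfg)
        row <- as.data.frame(rep_)
        row$family <- fam
        row$target_transitivity <- tt
        row$replicate <- r
        row$ssi <- equilibrium_ssi(tr)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("family", "target_transitivity", "replicate", "n_nodes",
                 "n_edges", "sffi", "apl", "diameter", "acc",
                 "transitivity", "modularity", "ssi")]
  attr(out, "config") <- config
  out
}
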