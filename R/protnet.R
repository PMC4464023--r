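#' Simulation configuration for a pseudocell
#'
#' Collects the lattice geometry, kinetic probabilities and run length of a
#' pseudocell simulation. The defaults are the reference experimental
#' settings: a 50-site cubic lattice (125000 sites), 20% occupancy,
#' bond-formation probability 0.7, bond-breaking probability 0.002 and
#' 150000 steps.
#'
#' @param L Lattice linear size (sites per edge), >= 2 (>= 3 for periodic
#'   boundaries).
#' @param occupancy Fraction of sites holding a protein instance, in
#'   `(0, 1]`.
#' @param p_on Probability of forming a bond per eligible face-adjacent
#'   pair per site visit.
#' @param p_off Probability of breaking each existing bond per site visit.
#' @param n_steps Number of simulation steps (interaction + diffusion).
#' @param seed Integer seed; every run with the same network, config and
#'   seed yields the same trajectory.
#' @param boundary `"periodic"` (default; avoids wall artifacts) or
#'   `"closed"`.
#' @param move_law Complex translation probability: `"mass"` (1/mass,
#'   default) or `"diameter"` (1/diameter).
#' @param record_every Snapshot interval in steps for [protnet_run()].
#' @return A list of class `"protnet_config"`.
#' @export
protnet_config <- function(L = 50, occupancy = 0.2, p_on = 0.7,
                           p_off = 0.002, n_steps = 150000, seed = 1,
                           boundary = c("periodic", "closed"),
                           move_law = c("mass", "diameter"),
                           record_every = 1000) {
  boundary <- match.arg(boundary)
  move_law <- match.arg(move_law)
  stopifnot(L >= 2, occupancy >= 0, occupancy <= 1,
            p_on >= 0, p_on <= 1, p_off >= 0, p_off <= 1,
            n_steps >= 0, record_every >= 1)
  structure(list(L = L, occupancy = occupancy, p_on = p_on, p_off = p_off,
                 n_steps = n_steps, seed = seed, boundary = boundary,
                 move_law = move_law, record_every = record_every),
            class = "protnet_config")
}

#' Named configuration profiles
#'
#' `"paper"` is the full reference configuration (L = 50, 150000 steps);
#' `"desk"` is a scaled-down profile (L = 12, 20000 steps, snapshots every
#' 500 steps) sized for interactive work and test suites, where the
#' qualitative contrasts of the full-scale experiments are already
#' detectable.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... Overrides passed to [protnet_config()].
#' @return A `protnet_config`.
#' @export
protnet_profile <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    paper = list(L = 50, n_steps = 150000, record_every = 1000),
    desk = list(L = 12, n_steps = 20000, record_every = 500))
  args <- utils::modifyList(base, list(...))
  do.call(protnet_config, args)
}

#' Read a simulation configuration from a flat key-value file
#'
#' Lines of the form `key = value` (or `key value`), `#` comments ignored.
#' Recognized keys: `lattice_size` (or `L`), `occupancy`, `p_on`, `p_off`,
#' `steps` (or `n_steps`), `seed`, `boundary`, `move_law`, `record_every`.
#'
#' @param path Configuration file path.
#' @return A [protnet_config()].
#' @export
read_protnet_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(trimws(lines), "\\s*=\\s*|\\s+")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
  alias <- c(lattice_size = "L", steps = "n_steps")
  names(vals) <- ifelse(names(vals) %in% names(alias),
                        alias[names(vals)], names(vals))
  known <- names(formals(protnet_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- as.list(vals)
  for (k in setdiff(names(args), c("boundary", "move_law"))) {
    args[[k]] <- as.numeric(args[[k]])
  }
  do.call(protnet_config, args)
}

# Convert an igraph rule network to the internal (names, 0-based edge
# matrix) pair used by the C++ core.
network_rules <- function(network) {
  stopifnot(igraph::is_igraph(network))
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(network)))
  el <- igraph::as_edgelist(network, names = FALSE)
  list(species = nm, edges = matrix(as.integer(el - 1L), ncol = 2))
}

#' Create a pseudocell simulation
#'
#' Builds the lattice, distributes equal copy numbers of every protein
#' species uniformly at random over the sites (remainder copies assigned to
#' randomly chosen species), assigns uniform random orientations and no
#' bonds, and returns a stateful simulation handle.
#'
#' @param network An undirected `igraph` graph whose vertices are protein
#'   species and whose edges are the binding rules (loops allowed: a
#'   species that can bind a copy of itself).
#' @param config A [protnet_config()].
#' @param fill If `FALSE`, create an empty lattice (instances are then
#'   placed explicitly with [sim_place()]).
#' @return An object of class `"protnet_sim"`.
#' @examples
#' g <- make_fixture_network("ring_of_cliques", 3)
#' sim <- protnet_sim(g, protnet_config(L = 8, n_steps = 10, seed = 1))
#' sim_step(sim, 10)
#' head(complexes(sim))
#' @export
protnet_sim <- function(network, config = protnet_config(), fill = TRUE) {
  stopifnot(inherits(config, "protnet_config"))
  rules <- network_rules(network)
  if (fill && config$occupancy * config$L^3 < 1) {
    stop("occupancy x L^3 must be at least 1")
  }
  ptr <- cpp_sim_new(length(rules$species), rules$edges, config$L,
                     config$boundary == "periodic", config$p_on,
                     config$p_off, config$move_law == "diameter",
                     config$occupancy, as.double(config$seed), fill)
  structure(list(ptr = ptr, species = rules$species, config = config),
            class = "protnet_sim")
}

#' Advance, inspect and manipulate a running simulation
#'
#' `sim_step` advances `n` full steps (interaction phase then diffusion
#' phase each); `sim_interaction_phase`/`sim_diffusion_phase` run a single
#' phase, for fine-grained testing. `sim_state` returns the complete
#' configuration; `complexes` the current complex records. `sim_place`
#' inserts a monomer of a given species at given 0-based lattice
#' coordinates; `sim_bond` creates a bond between two face-adjacent
#' instances subject to the usual legality rules (used to build controlled
#' states in tests and demos).
#'
#' @param sim A `protnet_sim`.
#' @param n Number of steps.
#' @return `sim_state`: a list with per-instance vectors `species`, `x`,
#'   `y`, `z` (0-based coordinates), `orientation`, `complex` and a 2-column
#'   matrix `bonds` of instance indices. `complexes`: a `data.frame` with
#'   columns `mass`, `diameter` and a list-column `composition` of species
#'   name vectors.
#' @export
sim_step <- function(sim, n = 1) {
  cpp_sim_step(sim$ptr, as.integer(n))
  invisible(sim)
}

#' @rdname sim_step
#' @export
sim_interaction_phase <- function(sim) {
  cpp_sim_interaction(sim$ptr)
  invisible(sim)
}

#' @rdname sim_step
#' @export
sim_diffusion_phase <- function(sim) {
  cpp_sim_diffusion(sim$ptr)
  invisible(sim)
}

#' @rdname sim_step
#' @export
sim_state <- function(sim) {
  st <- cpp_sim_state(sim$ptr)
  st$species_name <- sim$species[st$species]
  st
}

#' @rdname sim_step
#' @export
complexes <- function(sim) {
  cx <- cpp_sim_complexes(sim$ptr)
  data.frame(
    mass = cx$mass,
    diameter = cx$diameter,
    composition = I(lapply(cx$species, function(s) sim$species[s])),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_step
#' @param species Species name (or index) for `sim_place`.
#' @param x,y,z 0-based lattice coordinates.
#' @export
sim_place <- function(sim, species, x, y, z) {
  idx <- if (is.character(species)) match(species, sim$species)
         else as.integer(species)
  if (is.na(idx)) stop("unknown species: ", species)
  cpp_sim_place(sim$ptr, idx, as.integer(x), as.integer(y), as.integer(z))
}

#' @rdname sim_step
#' @param i,j Instance indices for `sim_bond`.
#' @export
sim_bond <- function(sim, i, j) {
  cpp_sim_bond(sim$ptr, as.integer(i), as.integer(j))
  invisible(sim)
}

#' @export
print.protnet_sim <- function(x, ...) {
  p <- cpp_sim_params(x$ptr)
  cat(sprintf(
    "Pseudocell simulation: L=%d (%d sites, %s), %d species, %d instances, step %d\n",
    p$L, p$L^3, if (p$periodic) "periodic" else "closed",
    p$n_species, p$n_instances, as.integer(p$step)))
  cat(sprintf("  p_on=%g p_off=%g move_law=%s\n", p$p_on, p$p_off,
              if (p$move_by_diameter) "diameter" else "mass"))
  invisible(x)
}

#' Run a pseudocell simulation and record complex snapshots
#'
#' Creates a simulation from `network` and `config`, advances it
#' `config$n_steps` steps and records the complex list (compositions and
#' masses, monomers included) at step 0, every `config$record_every` steps
#' and at the final step.
#'
#' @inheritParams protnet_sim
#' @return An object of class `"protnet_trace"`: a list with elements
#'   `config`, `species` and `snapshots` (each snapshot a list with `step`,
#'   `compositions` -- a list of sorted species-index vectors -- and
#'   `mass`).
#' @seealso [ssi_timeseries()], [equilibrium_ssi()], [write_snapshots()]
#' @export
protnet_run <- function(network, config = protnet_config()) {
  sim <- protnet_sim(network, config)
  snaps <- cpp_sim_run(sim$ptr, as.integer(config$n_steps),
                       as.integer(config$record_every))
  structure(list(config = config, species = sim$species, snapshots = snaps),
            class = "protnet_trace")
}

#' @export
print.protnet_trace <- function(x, ...) {
  ns <- length(x$snapshots)
  last <- x$snapshots[[ns]]
  cat(sprintf("Pseudocell trace: %d species, %d snapshots, final step %d\n",
              length(x$species), ns, as.integer(last$step)))
  cat(sprintf("  final: %d assemblies (%d complexes of >= 2 proteins)\n",
              length(last$mass), sum(last$mass > 1)))
  invisible(x)
}

#' @export
plot.protnet_trace <- function(x, include_monomers = FALSE, ...) {
  ts <- ssi_timeseries(x, include_monomers = include_monomers)
  plot(ts$step, ts$ssi, type = "l", xlab = "step", ylab = "SSI", ...)
  invisible(ts)
}

#' Equilibrium SSI of a trace
#'
#' The mean Self-Similarity Index over the final fraction `frac` of
#' recorded snapshots, used as the equilibrium summary of a run.
#'
#' @param trace A `protnet_trace`.
#' @param frac Final fraction of snapshots to average (default 0.1).
#' @param include_monomers Passed to [ssi_timeseries()].
#' @return A single number.
#' @export
equilibrium_ssi <- function(trace, frac = 0.1, include_monomers = FALSE) {
  ts <- ssi_timeseries(trace, include_monomers = include_monomers)
  k <- max(1L, ceiling(nrow(ts) * frac))
  mean(utils::tail(ts$ssi, k))
}

#' Maximum SSI over a trace
#'
#' @inheritParams equilibrium_ssi
#' @return The maximum recorded SSI.
#' @export
max_ssi <- function(trace, include_monomers = FALSE) {
  max(ssi_timeseries(trace, include_monomers = include_monomers)$ssi)
}

#' Write trace snapshots as plain-text complex lists
#'
#' One file per snapshot (`snapshot_<step>.txt`) in the format read by
#' [read_complex_list()]: `#`-prefixed header lines with the step and
#' configuration, then one complex per line as tab-separated sorted species
#' names (single names are monomers).
#'
#' @param trace A `protnet_trace`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
write_snapshots <- function(trace, dir) {
  stopifnot(inherits(trace, "protnet_trace"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- trace$config
  paths <- vapply(trace$snapshots, function(sn) {
    path <- file.path(dir, sprintf("snapshot_%08d.txt", as.integer(sn$step)))
    hdr <- c(sprintf("# step %d", as.integer(sn$step)),
             sprintf("# L=%d occupancy=%g p_on=%g p_off=%g seed=%s boundary=%s move_law=%s",
                     cfg$L, cfg$occupancy, cfg$p_on, cfg$p_off,
                     format(cfg$seed), cfg$boundary, cfg$move_law))
    body <- vapply(sn$compositions,
                   function(s) paste(trace$species[s], collapse = "\t"), "")
    writeLines(c(hdr, body), path)
    path
  }, "")
  invisible(paths)
}
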