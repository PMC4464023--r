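# network with two species A-B used by several tests
ab_network <- function() {
  igraph::graph_from_edgelist(cbind("A", "B"), directed = FALSE)
}

test_that("initialization fills the lattice with equal copy numbers", {
  g <- make_fixture_network("ring_of_cliques", 2, clique_size = 5)  # 10 species
  sim <- protnet_sim(g, protnet_config(L = 10, occupancy = 0.5, seed = 1,
                                       n_steps = 0))
  st <- sim_state(sim)
  expect_equal(length(st$species), 500)            # 0.5 * 1000
  expect_equal(unname(table(st$species)), rep(50L, 10), ignore_attr = TRUE)
  expect_equal(nrow(st$bonds), 0)
  # no two instances share a site
  expect_false(anyDuplicated(paste(st$x, st$y, st$z)) > 0)
  # orientations spread over the 24 rotations
  expect_gt(length(unique(st$orientation)), 20)

  # the reference full-scale geometry: 25000 instances on 125000 sites
  sim50 <- protnet_sim(g, protnet_config(L = 50, occupancy = 0.2, seed = 1))
  expect_equal(length(sim_state(sim50)$species), 25000)

  expect_error(protnet_sim(g, protnet_config(L = 10, occupancy = 0, seed = 1)),
               "at least 1")
  # more species than instances is impossible
  expect_error(protnet_sim(make_fixture_network("ring_of_cliques", 8),
                           protnet_config(L = 3, occupancy = 0.2, seed = 1,
                                          boundary = "closed")),
               "below the number of species")
})

test_that("p_on = 0 never forms a bond; all complexes stay monomers", {
  g <- make_fixture_network("clique_chain", 3)
  sim <- protnet_sim(g, protnet_config(L = 8, occupancy = 0.3, p_on = 0,
                                       seed = 5, n_steps = 0))
  sim_step(sim, 100)
  st <- sim_state(sim)
  expect_equal(nrow(st$bonds), 0)
  cx <- complexes(sim)
  expect_true(all(cx$mass == 1))
  expect_equal(nrow(cx), length(st$species))
})

test_that("an adjacent interacting pair with p_off = 0 dimerizes for good", {
  sim <- protnet_sim(ab_network(),
                     protnet_config(L = 4, occupancy = 0.5, p_on = 0.7,
                                    p_off = 0, seed = 2, boundary = "closed"),
                     fill = FALSE)
  sim_place(sim, "A", 1, 1, 1)
  sim_place(sim, "B", 2, 1, 1)
  bonded_at <- NA
  for (i in 1:50) {
    sim_step(sim, 1)
    if (nrow(sim_state(sim)$bonds) == 1) { bonded_at <- i; break }
  }
  expect_false(is.na(bonded_at))
  sim_step(sim, 200)
  st <- sim_state(sim)
  expect_equal(nrow(st$bonds), 1)          # absorbing state
  cx <- complexes(sim)
  expect_equal(sort(cx$mass), 2)
})

test_that("trajectories are deterministic in (network, config, seed)", {
  g <- make_fixture_network("ring_of_cliques", 4)
  cfg <- protnet_config(L = 8, occupancy = 0.25, seed = 99, n_steps = 0)
  s1 <- protnet_sim(g, cfg); sim_step(s1, 60)
  s2 <- protnet_sim(g, cfg); sim_step(s2, 60)
  expect_identical(sim_state(s1), sim_state(s2))
  cfg2 <- cfg; cfg2$seed <- 100
  s3 <- protnet_sim(g, cfg2); sim_step(s3, 60)
  expect_false(identical(sim_state(s1)[c("x", "y", "z")],
                         sim_state(s3)[c("x", "y", "z")]))
})

test_that("conservation, exclusion and bond legality hold along a run", {
  g <- make_fixture_network("ring_of_cliques", 5, clique_size = 4)
  cfg <- protnet_config(L = 8, occupancy = 0.3, p_on = 0.8, p_off = 0.01,
                        seed = 17, n_steps = 0)
  sim <- protnet_sim(g, cfg)
  st0 <- sim_state(sim)
  counts0 <- table(st0$species_name)
  for (chunk in 1:10) {
    sim_step(sim, 25)
    st <- sim_state(sim)
    expect_equal(table(st$species_name), counts0)           # conservation
    expect_false(anyDuplicated(paste(st$x, st$y, st$z)) > 0) # exclusion
    expect_true(protnet:::cpp_sim_check(sim$ptr))            # full audit
  }
})

test_that("a single monomer diffuses uniformly to its six neighbours", {
  sim <- protnet_sim(ab_network(),
                     protnet_config(L = 3, occupancy = 0.1, seed = 123,
                                    boundary = "closed"),
                     fill = FALSE)
  id <- sim_place(sim, "A", 1, 1, 1)
  moves <- integer(6)
  names(moves) <- c("+x", "-x", "+y", "-y", "+z", "-z")
  for (i in 1:6000) {
    sim_diffusion_phase(sim)
    st <- sim_state(sim)
    d <- c(st$x - 1, st$y - 1, st$z - 1)
    k <- which(d != 0)
    expect_length(k, 1)   # always moves exactly one site from the centre
    moves[2 * k - (d[k] > 0)] <- moves[2 * k - (d[k] > 0)] + 1
    cpp <- protnet:::cpp_sim_move(sim$ptr, id, 1L, 1L, 1L)
  }
  expect_gt(stats::chisq.test(moves)$p.value, 0.01)
})

test_that("a rigid dimer keeps its bond and adjacency while diffusing", {
  sim <- protnet_sim(ab_network(),
                     protnet_config(L = 6, occupancy = 0.1, p_on = 0,
                                    p_off = 0, seed = 8),
                     fill = FALSE)
  sim_place(sim, "A", 2, 2, 2)
  sim_place(sim, "B", 3, 2, 2)
  sim_bond(sim, 1, 2)
  for (i in 1:500) sim_diffusion_phase(sim)
  st <- sim_state(sim)
  expect_equal(nrow(st$bonds), 1)
  d <- abs(c(st$x[1] - st$x[2], st$y[1] - st$y[2], st$z[1] - st$z[2]))
  d <- pmin(d, 6 - d)   # periodic minimal image
  expect_equal(sort(d), c(0, 0, 1))   # still face-adjacent
  expect_true(protnet:::cpp_sim_check(sim$ptr))
})

test_that("complex partition equals independent connected components", {
  # build a legal bonded configuration on a chain network and compare the
  # simulator's partition to igraph components of the bond graph
  n <- 24
  ring <- igraph::make_ring(n)
  igraph::V(ring)$name <- paste0("S", seq_len(n))
  sim <- protnet_sim(ring, protnet_config(L = 10, occupancy = 0.1, seed = 3,
                                          boundary = "closed"),
                     fill = FALSE)
  # place species along a line so consecutive species are adjacent
  for (i in seq_len(n)) {
    sim_place(sim, paste0("S", i), (i - 1) %% 10, (i - 1) %/% 10, 0)
  }
  set.seed(44)
  bonded <- c()
  for (i in seq_len(n - 1)) {
    if ((i %% 10) == 0) next        # row breaks are not adjacent
    if (runif(1) < 0.5) {
      sim_bond(sim, i, i + 1)
      bonded <- c(bonded, i)
    }
  }
  st <- sim_state(sim)
  bg <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(st$bonds) > 0) bg <- igraph::add_edges(bg, t(st$bonds))
  oracle <- igraph::components(bg)$membership
  expect_equal(length(unique(st$complex)), max(oracle))
  # same partition up to labels
  expect_equal(unname(split(seq_len(n), st$complex)[order(vapply(split(seq_len(n), st$complex), min, 1))]),
               unname(split(seq_len(n), oracle)[order(vapply(split(seq_len(n), oracle), min, 1))]))
  expect_true(protnet:::cpp_sim_check(sim$ptr))
})

test_that("empirical state frequencies match the exact two-protein chain", {
  # 2x2x2 closed lattice, one A and one B with an A-B rule; parameters
  # chosen for fast mixing so thinned samples are near-independent
  p_on <- 0.7; p_off <- 0.2
  chain <- mc_build_chain(p_on, p_off)
  probs <- mc_category_probs(chain)
  sim <- protnet_sim(ab_network(),
                     protnet_config(L = 2, occupancy = 0.25, p_on = p_on,
                                    p_off = p_off, seed = 4242,
                                    boundary = "closed"),
                     fill = FALSE)
  sim_place(sim, "A", 0, 0, 0)
  sim_place(sim, "B", 1, 1, 1)
  sim_step(sim, 500)                       # burn-in
  thin <- 25
  n_samp <- 4000                           # 500 + 4000*25 ~ 1e5 steps
  obs <- c(bonded = 0, adjacent = 0, apart = 0)
  for (i in seq_len(n_samp)) {
    sim_step(sim, thin)
    st <- sim_state(sim)
    pa <- mc_site(st$x[1], st$y[1], st$z[1])
    pb <- mc_site(st$x[2], st$y[2], st$z[2])
    cat_ <- mc_category(pa, pb, as.integer(nrow(st$bonds) > 0))
    obs[cat_] <- obs[cat_] + 1
  }
  expect_gt(stats::chisq.test(obs, p = probs[names(obs)])$p.value, 0.01)
})

test_that("the bonded fraction at reference kinetics matches the exact chain", {
  # the reference kinetic setting (p_on 0.7, p_off 0.002) is strongly
  # bond-dominated; compare the long-run bonded fraction to the exact
  # stationary probability with a generous correlated-sample margin
  chain <- mc_build_chain(0.7, 0.002)
  p_bond <- mc_category_probs(chain)["bonded"]
  sim <- protnet_sim(ab_network(),
                     protnet_config(L = 2, occupancy = 0.25, p_on = 0.7,
                                    p_off = 0.002, seed = 77,
                                    boundary = "closed"),
                     fill = FALSE)
  sim_place(sim, "A", 0, 0, 0)
  sim_place(sim, "B", 1, 1, 1)
  sim_step(sim, 2000)
  hits <- 0; n_samp <- 600; thin <- 50
  for (i in seq_len(n_samp)) {
    sim_step(sim, thin)
    hits <- hits + (nrow(sim_state(sim)$bonds) > 0)
  }
  expect_lt(abs(hits / n_samp - p_bond), 0.05)
})

test_that("raising p_off lowers the equilibrium mean complex mass", {
  g <- make_fixture_network("ring_of_cliques", 6, clique_size = 5)
  mean_mass <- vapply(c(0.002, 0.02, 0.2), function(poff) {
    cfg <- protnet_config(L = 8, occupancy = 0.25, p_on = 0.7, p_off = poff,
                          seed = 31, n_steps = 0)
    sim <- protnet_sim(g, cfg)
    sim_step(sim, 600)
    masses <- c()
    for (i in 1:10) { sim_step(sim, 20); masses <- c(masses, complexes(sim)$mass) }
    mean(masses)
  }, 1)
  expect_gt(mean_mass[1], mean_mass[3])
  expect_gte(mean_mass[1], mean_mass[2] * 0.95)
  expect_gte(mean_mass[2], mean_mass[3] * 0.95)
})

test_that("species uniqueness caps complex composition", {
  g <- make_fixture_network("ring_of_cliques", 4, clique_size = 5)
  sim <- protnet_sim(g, protnet_config(L = 8, occupancy = 0.3, p_on = 1,
                                       p_off = 0, seed = 12, n_steps = 0))
  sim_step(sim, 150)
  cx <- complexes(sim)
  expect_true(all(vapply(cx$composition, function(s) !anyDuplicated(s), TRUE)))
  expect_true(all(cx$mass <= 20))          # at most one copy of each species
  expect_true(all(vapply(seq_len(nrow(cx)),
                         function(i) cx$mass[i] == length(cx$composition[[i]]),
                         TRUE)))
})

test_that("protnet_run records snapshots and zero steps keeps the start", {
  g <- make_fixture_network("clique_chain", 2)
  cfg <- protnet_config(L = 6, occupancy = 0.3, n_steps = 0, seed = 1)
  tr <- protnet_run(g, cfg)
  expect_length(tr$snapshots, 1)
  expect_equal(tr$snapshots[[1]]$step, 0)
  expect_true(all(tr$snapshots[[1]]$mass == 1))

  cfg$n_steps <- 120; cfg$record_every <- 40
  tr2 <- protnet_run(g, cfg)
  expect_equal(vapply(tr2$snapshots, function(s) s$step, 1), c(0, 40, 80, 120))
  # instance conservation across snapshots
  tot <- vapply(tr2$snapshots, function(s) sum(s$mass), 1)
  expect_true(all(tot == tot[1]))
})

test_that("snapshots round-trip through the plain-text format", {
  g <- make_fixture_network("ring_of_cliques", 3)
  cfg <- protnet_config(L = 7, occupancy = 0.3, n_steps = 60, seed = 6,
                        record_every = 30)
  tr <- protnet_run(g, cfg)
  dir <- withr::local_tempdir()
  paths <- write_snapshots(tr, dir)
  expect_length(paths, length(tr$snapshots))
  last <- tr$snapshots[[length(tr$snapshots)]]
  cell <- read_complex_list(paths[length(paths)], include_monomers = TRUE)
  expect_equal(length(cell), length(last$compositions))
  got <- sort(vapply(cell, function(x) paste(sort(x), collapse = "+"), ""))
  want <- sort(vapply(last$compositions,
                      function(s) paste(sort(tr$species[s]), collapse = "+"), ""))
  expect_equal(got, want)
})

test_that("key-value config files map onto protnet_config", {
  tf <- withr::local_tempfile()
  writeLines(c("# demo configuration", "lattice_size = 12", "occupancy 0.2",
               "p_on = 0.7", "p_off = 0.002", "steps = 100", "seed = 9",
               "boundary = closed", "move_law = diameter",
               "record_every = 10"), tf)
  cfg <- read_protnet_config(tf)
  expect_equal(cfg$L, 12)
  expect_equal(cfg$n_steps, 100)
  expect_equal(cfg$boundary, "closed")
  expect_equal(cfg$move_law, "diameter")
  writeLines("warp_speed = 9", tf)
  expect_error(read_protnet_config(tf), "unknown config key")
})
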