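test_that("the Similarity Index formula matches hand-worked cases", {
  # identical sets of size k -> k^2
  expect_equal(similarity_index(c("A", "B", "C"), c("A", "B", "C")), 9)
  expect_equal(similarity_index("A", "A"), 1)
  # disjoint -> 0
  expect_equal(similarity_index(c("A", "B"), c("C", "D")), 0)
  # partial overlap: |{B,C}|^2 / (|{A,D}| + 1)
  expect_equal(similarity_index(c("A", "B", "C"), c("B", "C", "D")), 4 / 3)
  expect_error(similarity_index(character(0), "A"), "empty")
})

test_that("S.I. is symmetric and the C++ matrix agrees with the R formula", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_cell(1)[[1]]
    b <- random_cell(1)[[1]]
    expect_equal(similarity_index(a, b), similarity_index(b, a))
  }
  cell_a <- random_cell(6)
  cell_b <- random_cell(5)
  M <- similarity_matrix(cell_a, cell_b)
  expect_equal(dim(M), c(6, 5))
  for (i in 1:6) for (j in 1:5) {
    expect_equal(M[i, j], similarity_index(cell_a[[i]], cell_b[[j]]))
  }
  # self-similarity diagonal = |C|^2
  Ms <- similarity_matrix(cell_a)
  expect_equal(diag(Ms), vapply(cell_a, function(x) length(unique(x))^2, 1))
})

test_that("SSI matches direct evaluation of the formula", {
  # two identical dimers: (4)/2 = 2
  expect_equal(self_similarity_index(list(c("A", "B"), c("A", "B"))), 2)
  # pairwise-disjoint complexes: 0
  expect_equal(self_similarity_index(list(c("A", "B"), c("C", "D"), c("E", "F"))), 0)
  # canonical order [{A,B,C},{B,C,D},{X,Y}]: (max(4/3, 0) + 0) / 3
  cell <- list(c("X", "Y"), c("B", "C", "D"), c("A", "B", "C"))
  expect_equal(self_similarity_index(cell), 4 / 9)
  # n identical complexes of size k: k^2 (n-1) / n
  for (n in c(2, 5, 9)) {
    cell <- rep(list(c("A", "B", "C")), n)
    expect_equal(self_similarity_index(cell), 9 * (n - 1) / n)
  }
  expect_warning(ssi1 <- self_similarity_index(list(c("A", "B"))), "fewer than 2")
  expect_equal(ssi1, 0)
})

test_that("a cell compared against itself attains the maximal ICSI", {
  # S.I.(C, D) <= |C|^2 with equality iff C == D, so greedy self-matching
  # recovers the mean squared complex size exactly
  set.seed(57)
  for (trial in 1:10) {
    cell <- random_cell(sample(2:6, 1))
    expect_equal(inter_cell_similarity_index(cell, cell),
                 mean(vapply(cell, function(x) length(unique(x))^2, 1)))
  }
})

test_that("the symmetric SSI variant is order-free and bounds the literal one", {
  set.seed(73)
  cell <- random_cell(6)
  lit <- self_similarity_index(cell)
  sym <- self_similarity_index(cell, symmetric = TRUE)
  expect_gte(sym, lit - 1e-12)
  perm <- sample(length(cell))
  expect_equal(self_similarity_index(cell[perm], symmetric = TRUE), sym)
  # canonical ordering makes the literal form permutation-invariant too
  expect_equal(self_similarity_index(cell[perm]), lit)
})

test_that("ICSI reproduces the greedy trace on worked examples", {
  a <- list(c("A", "B"), c("C", "D", "E"))
  out <- inter_cell_similarity_index(a, a, detail = TRUE)
  expect_equal(out$scores, c(9, 4))   # largest S.I. first
  expect_equal(out$icsi, 6.5)
  # compositionally disjoint cells
  b <- list(c("X", "Y"), c("Z", "W"))
  expect_equal(inter_cell_similarity_index(a, b), 0)
  expect_error(inter_cell_similarity_index(a, list()), "empty")
  # rectangular: only min(n, m) matches are scored
  c3 <- list(c("A", "B"), c("A", "B"), c("C", "D"))
  out2 <- inter_cell_similarity_index(list(c("A", "B")), c3, detail = TRUE)
  expect_equal(length(out2$scores), 1)
  expect_equal(out2$icsi, 4)
})

test_that("greedy ICSI never exceeds the exhaustive optimal assignment", {
  set.seed(91)
  n_equal <- 0
  trials <- 40
  for (t in 1:trials) {
    cell_a <- random_cell(sample(2:6, 1))
    cell_b <- random_cell(sample(2:6, 1))
    M <- similarity_matrix(cell_a, cell_b)
    greedy <- inter_cell_similarity_index(cell_a, cell_b)
    opt <- oracle_optimal_assignment(M)
    expect_lte(greedy, opt + 1e-12)
    if (abs(greedy - opt) < 1e-12) n_equal <- n_equal + 1
  }
  expect_gte(n_equal / trials, 0.8)
})

test_that("snapshot files round-trip through read_complex_list", {
  tf <- withr::local_tempfile()
  writeLines(c("# step 100", "A\tB\tC", "D\tE", "F"), tf)
  cell <- read_complex_list(tf)
  expect_equal(cell, list(c("A", "B", "C"), c("D", "E")))
  with_mono <- read_complex_list(tf, include_monomers = TRUE)
  expect_equal(length(with_mono), 3)
  writeLines(c("A\tA"), tf)    # duplicated species in one complex
  expect_error(read_complex_list(tf), "malformed")
})

test_that("ssi_timeseries follows the closed form on a synthetic trace", {
  # snapshot t has 2^t identical {A,B} dimers: SSI = 4 (n-1) / n -> 4
  snaps <- lapply(0:4, function(t) {
    n <- 2^t
    list(step = t, compositions = rep(list(c(1L, 2L)), n),
         mass = rep(2L, n))
  })
  trace <- structure(list(config = protnet_config(n_steps = 0),
                          species = c("A", "B"), snapshots = snaps),
                     class = "protnet_trace")
  ts <- suppressWarnings(ssi_timeseries(trace))
  n <- 2^(0:4)
  expect_equal(ts$ssi, ifelse(n < 2, 0, 4 * (n - 1) / n))
  expect_equal(ts$n_complexes, n)
})
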