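test_that("elimination order starts at minimal degree and controls boundaries", {
  g1 <- toy_graph(1, list())
  eo1 <- elimination_order(g1)
  expect_equal(eo1$order, 1L)
  expect_equal(eo1$boundary_sizes, 0L)
  # path: produced order keeps the boundary at size <= 1
  eo <- elimination_order(path_graph(12))
  expect_lte(max(eo$boundary_sizes), 1L)
  # cycle of length 6: boundary reaches exactly 2
  eo6 <- elimination_order(cycle_graph(6))
  expect_equal(max(eo6$boundary_sizes), 2L)
  # first node has globally minimal degree
  g <- toy_graph(4, list(c(1, 2), c(2, 3), c(3, 4), c(2, 4)))
  expect_equal(elimination_order(g)$order[1], 1L)
})

test_that("single node and all-zero potentials decode as specified", {
  g1 <- toy_graph(1, list())
  p1 <- structure(list(node = matrix(c(0, 1), 1, 2), edge = matrix(0, 0, 4),
                       edges = matrix(0L, 0, 2)), class = "potential_table")
  d <- viterbi_decode(g1, p1)
  expect_equal(d$labels, "I")
  expect_equal(d$score, 1)
  # ties prefer N everywhere
  set.seed(2)
  g <- random_graph(8, 0.3)
  pot <- random_potentials(g); pot$node[] <- 0; pot$edge[] <- 0
  d0 <- viterbi_decode(g, pot)
  expect_equal(d0$score, 0)
  expect_true(all(d0$labels == "N"))
})

test_that("unlimited-beam decoding equals exhaustive enumeration on random graphs", {
  set.seed(123)
  for (r in 1:60) {
    g <- random_graph(sample(2:10, 1), 0.3)
    pot <- random_potentials(g)
    dec <- viterbi_decode(g, pot)
    oracle <- brute_force_map(pot)
    expect_equal(dec$score, oracle$score, tolerance = 1e-10)
    expect_equal(ifelse(dec$labels == "I", 1L, 0L), oracle$y)
    expect_true(dec$exact)
    # reported score is the score of the reported assignment
    expect_equal(assignment_score(dec$labels, pot), dec$score)
  }
})

test_that("path graphs reproduce classical linear-chain Viterbi", {
  set.seed(44)
  for (n in c(5, 20, 50)) {
    g <- path_graph(n)
    pot <- random_potentials(g)
    dec <- viterbi_decode(g, pot)
    oracle <- chain_viterbi(pot$node, pot$edge)
    expect_equal(dec$score, oracle$score, tolerance = 1e-10)
    expect_equal(ifelse(dec$labels == "I", 1L, 0L), oracle$y)
  }
})

test_that("a leaf-to-root order on a tree keeps boundaries at size one", {
  # balanced binary tree on 15 nodes, children before parents
  edges <- lapply(2:15, function(k) c(k %/% 2, k))
  g <- toy_graph(15, edges)
  leaf_to_root <- 15:1
  expect_lte(max(replay_boundary_sizes(g, leaf_to_root)), 1L)
  # decoding along that order still matches enumeration
  set.seed(5)
  pot <- random_potentials(g)
  dec <- viterbi_decode(g, pot, order = leaf_to_root)
  expect_equal(dec$score, brute_force_map(pot)$score, tolerance = 1e-10)
})

test_that("beam pruning is sound and exact when the budget covers the boundary", {
  set.seed(77)
  for (r in 1:15) {
    g <- random_graph(9, 0.4)
    pot <- random_potentials(g)
    exact <- viterbi_decode(g, pot)
    wide <- viterbi_decode(g, pot, beam = beam_config(2^12, seed = r))
    expect_equal(wide$score, exact$score, tolerance = 1e-10)
    narrow <- viterbi_decode(g, pot, beam = beam_config(2, seed = r))
    expect_lte(narrow$score, exact$score + 1e-10)
    expect_equal(assignment_score(narrow$labels, pot), narrow$score)
  }
})

test_that("prune_table follows the percentile contract", {
  bm <- beam_config(8, seed = 1)
  small <- prune_table(keys = 0:3, values = c(1, 2, 3, 4), bm)
  expect_equal(small$values, c(1, 2, 3, 4))  # within budget: untouched
  bm2 <- beam_config(2, seed = 1)
  top2 <- prune_table(keys = 0:3, values = c(1, 2, 3, 4), bm2)
  expect_setequal(top2$values, c(3, 4))      # small-table exact path
  # large-table sampling path: retained minimum exceeds the estimated percentile
  set.seed(99)
  vals <- rnorm(20000)
  bm3 <- beam_config(5000, seed = 42, sample_size = 2048)
  pr <- prune_table(seq_along(vals) - 1, vals, bm3)
  expect_lt(length(pr$values), length(vals))
  expect_gte(length(pr$values), 1)
  # every retained value beats every clearly-discarded low value
  expect_gt(min(pr$values), stats::quantile(vals, 0.5))
})

test_that("forward pass matches the exhaustive partition function", {
  set.seed(202)
  # all-zero potentials: Z = 2^n
  g <- random_graph(7, 0.35)
  pot <- random_potentials(g); pot$node[] <- 0; pot$edge[] <- 0
  expect_equal(forward_pass(g, pot)$log_Z, 7 * log(2), tolerance = 1e-12)
  # single node closed form
  g1 <- toy_graph(1, list())
  p1 <- structure(list(node = matrix(c(0.4, -1.2), 1, 2), edge = matrix(0, 0, 4),
                       edges = matrix(0L, 0, 2)), class = "potential_table")
  expect_equal(forward_pass(g1, p1)$log_Z, log(exp(0.4) + exp(-1.2)),
               tolerance = 1e-12)
  for (r in 1:20) {
    g <- random_graph(sample(2:10, 1), 0.3)
    pot <- random_potentials(g)
    fw <- forward_pass(g, pot)
    lz <- surfcrf:::.logsumexp(conditional_distribution_bruteforce(pot)$score)
    expect_equal(fw$log_Z, lz, tolerance = 1e-9)
    # log Z >= MAP score; exp(MAP - log Z) is the MAP probability
    dec <- viterbi_decode(g, pot)
    expect_gte(fw$log_Z, dec$score)
    d <- conditional_distribution_bruteforce(pot)
    expect_equal(exp(dec$score - fw$log_Z), max(d$prob), tolerance = 1e-9)
  }
})

test_that("dummy-node augmentation leaves log Z unchanged", {
  set.seed(55)
  for (r in 1:10) {
    g <- random_graph(sample(4:10, 1), 0.35)
    pot <- random_potentials(g)
    with_aug <- forward_pass(g, pot, augment = TRUE, keep_grid = FALSE)
    without <- forward_pass(g, pot, augment = FALSE, keep_grid = FALSE)
    expect_equal(with_aug$log_Z, without$log_Z, tolerance = 1e-9)
  }
  # bounded beams are refused
  g <- random_graph(6, 0.4)
  expect_error(forward_pass(g, random_potentials(g),
                            beam = beam_config(4, seed = 1)), "refused")
})

test_that("posterior sampling draws from the exact posterior", {
  # single node, symmetric potentials: I frequency near 1/2
  g1 <- toy_graph(1, list())
  p_eq <- structure(list(node = matrix(c(0.7, 0.7), 1, 2), edge = matrix(0, 0, 4),
                         edges = matrix(0L, 0, 2)), class = "potential_table")
  s <- sample_posterior(forward_pass(g1, p_eq), 10000, seed = 1)
  expect_lt(abs(mean(s) - 0.5), 3 * sqrt(0.25 / 10000))
  # near-deterministic node
  p_hi <- p_eq; p_hi$node[1, ] <- c(0, 20)
  expect_true(all(sample_posterior(forward_pass(g1, p_hi), 500, seed = 2) == 1))
  # n = 6: total-variation distance to the brute-force posterior
  set.seed(31)
  g <- random_graph(6, 0.4)
  pot <- random_potentials(g)
  fw <- forward_pass(g, pot)
  s <- sample_posterior(fw, 50000, seed = 7)
  emp <- tabulate(1 + s %*% 2^(0:5), nbins = 64) / nrow(s)
  d <- conditional_distribution_bruteforce(pot)
  expect_lt(0.5 * sum(abs(emp - d$prob)), 0.02)
})

test_that("posterior marginals agree between exact and sampling paths", {
  set.seed(61)
  g <- random_graph(6, 0.4)
  pot <- random_potentials(g)
  fw <- forward_pass(g, pot)
  exact <- posterior_marginals(fw, method = "exact")
  samp <- posterior_marginals(fw, method = "sampling", n_samples = 20000, seed = 3)
  expect_true(all(abs(exact$p_I - samp$p_I) <= 3 * pmax(samp$se, 1e-3)))
  # all-zero potentials: every marginal is exactly 1/2
  pot0 <- pot; pot0$node[] <- 0; pot0$edge[] <- 0
  m0 <- posterior_marginals(forward_pass(g, pot0), method = "exact")
  expect_equal(m0$p_I, rep(0.5, 6))
})

test_that("disconnected graphs decode componentwise to the global optimum", {
  set.seed(71)
  g <- toy_graph(6, list(c(1, 2), c(2, 3), c(4, 5), c(5, 6)))
  pot <- random_potentials(g)
  dec <- viterbi_decode(g, pot)
  expect_equal(dec$score, brute_force_map(pot)$score, tolerance = 1e-10)
  fw <- forward_pass(g, pot)
  lz <- surfcrf:::.logsumexp(conditional_distribution_bruteforce(pot)$score)
  expect_equal(fw$log_Z, lz, tolerance = 1e-9)
})
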