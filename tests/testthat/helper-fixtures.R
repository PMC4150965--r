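# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; oracles deliberately avoid the package's own code paths.

# bare surface graph on n nodes with the given undirected edge list
toy_graph <- function(n, edges) {
  nodes <- tibble::tibble(index = seq_len(n), chain = "A", resno = seq_len(n),
                          insert = "", resid = "ALA", rasa = NA_real_)
  if (length(edges)) {
    em <- do.call(rbind, lapply(edges, function(e) sort(e)))
    ed <- tibble::tibble(i = em[, 1], j = em[, 2], distance = 1)
  } else {
    ed <- tibble::tibble(i = integer(0), j = integer(0), distance = numeric(0))
  }
  surfcrf:::new_surface_graph(nodes, ed, "cgnk", 6)
}

path_graph <- function(n) {
  toy_graph(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

cycle_graph <- function(n) {
  toy_graph(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)), list(c(n, 1))))
}

# random connected-enough Erdos-Renyi graph without isolated nodes
random_graph <- function(n, p = 0.3) {
  repeat {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    if (all(rowSums(A) > 0)) break
  }
  idx <- which(upper.tri(A) & A, arr.ind = TRUE)
  toy_graph(n, lapply(seq_len(nrow(idx)), function(k) idx[k, ]))
}

random_potentials <- function(graph, sd = 1) {
  n <- surfcrf::n_positions(graph)
  m <- nrow(graph$edges)
  structure(list(
    node = matrix(stats::rnorm(2 * n, sd = sd), n, 2,
                  dimnames = list(NULL, c("N", "I"))),
    edge = matrix(stats::rnorm(4 * m, sd = sd), m, 4,
                  dimnames = list(NULL, c("NN", "IN", "NI", "II"))),
    edges = as.matrix(graph$edges[, c("i", "j")])),
    class = "potential_table")
}

# exhaustive-enumeration MAP oracle, independent of the package's decoder
brute_force_map <- function(potentials) {
  n <- nrow(potentials$node)
  best <- NULL
  for (key in 0:(2^n - 1)) {
    y <- as.integer(intToBits(key))[1:n]
    s <- sum(potentials$node[cbind(1:n, y + 1)])
    if (nrow(potentials$edges)) {
      p <- y[potentials$edges[, 1]] + 2L * y[potentials$edges[, 2]]
      s <- s + sum(potentials$edge[cbind(seq_len(nrow(potentials$edges)), p + 1)])
    }
    if (is.null(best) || s > best$score + 1e-12) best <- list(score = s, y = y)
  }
  best
}

# classical linear-chain Viterbi, written independently for path graphs whose
# edges are (i, i+1) in index order
chain_viterbi <- function(node_pot, edge_pot) {
  n <- nrow(node_pot)
  V <- matrix(-Inf, n, 2)
  bp <- matrix(0L, n, 2)
  V[1, ] <- node_pot[1, ]
  for (i in 2:n) {
    for (y in 0:1) {
      # edge i-1 -> i: pair index p = y_{i-1} + 2 * y_i
      cand <- V[i - 1, ] + edge_pot[i - 1, c(0, 1) + 2 * y + 1]
      V[i, y + 1] <- node_pot[i, y + 1] + max(cand)
      bp[i, y + 1] <- which.max(cand) - 1L
    }
  }
  y <- integer(n)
  y[n] <- which.max(V[n, ]) - 1L
  for (i in (n - 1):1) y[i] <- bp[i + 1, y[i + 1] + 1]
  list(score = max(V[n, ]), y = y)
}

# Monte-Carlo SASA oracle: fraction of random points on each expanded sphere
# not buried in any other expanded sphere (independent of Shrake-Rupley's
# deterministic lattice)
mc_sasa <- function(xyz, radii, probe = 1.4, n_points = 20000L) {
  n <- nrow(xyz)
  rr <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(n_points * 3), n_points, 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rr[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * mean(free)
  }
  out
}

# minimal PDB writer for synthetic test structures
write_tiny_pdb <- function(path, atoms) {
  # atoms: data.frame with chain, resno, resid, elety, elesy, x, y, z
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
    atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$elesy)
  writeLines(c(lines, "END"), path)
  path
}

# a small synthetic "dimer": two short strands of CA/CB pseudo-residues at a
# controllable gap, enough to exercise contact criteria
tiny_dimer_atoms <- function(gap = 4.0) {
  mk <- function(chain, x0) {
    do.call(rbind, lapply(1:3, function(k) {
      data.frame(chain = chain, resno = k, resid = "ALA",
                 elety = c("N", "CA", "C", "O", "CB"),
                 elesy = c("N", "C", "C", "O", "C"),
                 x = x0 + c(0, 0.5, 1.0, 1.5, 0.5),
                 y = (k - 1) * 3.8 + c(0, 0, 0.6, 0.6, 1.2),
                 z = c(0, 1.2, 1.2, 2.2, 2.4))
    }))
  }
  rbind(mk("A", 0), mk("B", 1.5 + gap))
}

instance_set <- function(m = 4, n = 60, seed = 1, sigma = 1.0,
                         interface_fraction = 0.2) {
  surfcrf::simulate_instances(
    m, n = n, expected_degree = 6, interface_fraction = interface_fraction,
    config = surfcrf::make_score_config(sigma = sigma), seed = seed)
}
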