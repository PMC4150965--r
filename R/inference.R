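#' Beam configuration for the generalized Viterbi heuristic
#'
#' The exact generalized Viterbi algorithm keeps one table entry per
#' reachable boundary assignment; its space is exponential in the largest
#' boundary. The beam heuristic caps the number of entries per table. When a
#' table exceeds the cap and is too large to sort exactly, the discard
#' percentile is estimated from a random sample of its entries and only
#' entries whose Viterbi value exceeds the estimated percentile are retained.
#'
#' @param max_entries Maximum table entries per boundary component
#'   (`Inf` = exact decoding). Default `2^16` when a cap is requested.
#' @param sample_size Sample size for percentile estimation (tables with at
#'   most 4096 entries are pruned by exact order statistics instead).
#' @param seed Integer seed for the percentile sampling; required whenever
#'   `max_entries` is finite.
#' @return A `beam_config`.
#' @export
beam_config <- function(max_entries = Inf, sample_size = 1024L, seed = NULL) {
  stopifnot(max_entries >= 1, sample_size >= 1)
  if (is.finite(max_entries) && is.null(seed)) {
    stop("a bounded beam requires an explicit seed")
  }
  structure(list(max_entries = max_entries, sample_size = as.integer(sample_size),
                 seed = seed),
            class = "beam_config")
}

#' Elimination order for generalized Viterbi decoding
#'
#' Builds the node order the decoder traverses. The order starts at a vertex
#' of globally minimal degree. At each step, among the current boundary nodes
#' (history nodes with untouched neighbours) the one with the fewest edges to
#' untouched nodes is selected, and its untouched neighbours are enqueued
#' next in index order. On a disconnected graph the procedure restarts from a
#' minimal-degree untouched node. Ties are broken by lower position index.
#'
#' @param graph A `surface_graph`.
#' @return A list with `order` (integer permutation) and `boundary_sizes`
#'   (per-step maximal boundary-component size, from
#'   [replay_boundary_sizes()]).
#' @export
elimination_order <- function(graph) {
  n <- n_positions(graph)
  adj <- .adjacency(graph)
  deg <- lengths(adj)
  touched <- logical(n)
  ord <- integer(0)
  push <- function(v) {
    touched[v] <<- TRUE
    ord[length(ord) + 1L] <<- v
  }
  while (length(ord) < n) {
    untouched <- which(!touched)
    bnd <- which(touched & vapply(seq_len(n), function(u)
      touched[u] && any(!touched[adj[[u]]]), logical(1)))
    if (!length(bnd)) {
      # fresh component: minimal-degree untouched node, lowest index on ties
      cand <- untouched[deg[untouched] == min(deg[untouched])]
      push(cand[1])
      next
    }
    nun <- vapply(bnd, function(u) sum(!touched[adj[[u]]]), integer(1))
    b <- bnd[nun == min(nun)][1]
    for (w in sort(adj[[b]][!touched[adj[[b]]]])) push(w)
  }
  list(order = ord, boundary_sizes = replay_boundary_sizes(graph, ord))
}

#' Boundary sizes along an elimination order
#'
#' Replays an order and reports, after each step, the size of the largest
#' boundary component: among the connected components of the history set, the
#' maximal number of member positions that still have an untouched
#' neighbour. Viterbi tables are indexed per component, so their sizes are
#' bounded by `2^b` for the largest such `b` along the order.
#'
#' @param graph A `surface_graph`.
#' @param order Integer permutation of positions.
#' @return Integer vector of per-step maximal boundary-component sizes.
#' @export
replay_boundary_sizes <- function(graph, order) {
  n <- n_positions(graph)
  stopifnot(length(order) == n, all(sort(order) == seq_len(n)))
  adj <- .adjacency(graph)
  gi <- igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  touched <- logical(n)
  out <- integer(n)
  for (s in seq_len(n)) {
    touched[order[s]] <- TRUE
    hist <- which(touched)
    sub <- igraph::induced_subgraph(gi, hist)
    memb <- igraph::components(sub)$membership
    on_boundary <- vapply(hist, function(u) any(!touched[adj[[u]]]), logical(1))
    out[s] <- if (any(on_boundary)) max(table(memb[on_boundary])) else 0L
  }
  out
}

# ---- shared pass engine ------------------------------------------------------
# mode "max": generalized Viterbi (raw potential space, group maxima with
#   backpointers); mode "sum": forward pass (log space, group log-sum-exp,
#   optionally keeping the per-stage joint grids for backward sampling).

.run_pass <- function(n, adj, node_pot, edge_pot, edge_idx, order, mode,
                      beam = beam_config(), keep_grid = FALSE) {
  dimnames(node_pot) <- NULL
  dimnames(edge_pot) <- NULL
  bounded <- is.finite(beam$max_entries)
  if (bounded) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(beam$seed)
  }
  processed <- logical(n)
  comp_of <- integer(n)           # 0 = untouched
  tables <- list()                # per live comp: keys, values, idx, boundary
  records <- vector("list", length(order))
  next_id <- 0L
  pruned_any <- FALSE

  for (step in seq_along(order)) {
    v <- order[step]
    processed[v] <- TRUE
    hnb <- adj[[v]][processed[adj[[v]]]]
    parents <- sort(unique(comp_of[hnb]))
    sizes <- vapply(parents, function(t) length(tables[[t]]$values), integer(1))

    if (bounded && length(parents)) {
      guard <- max(4 * beam$max_entries, 2^16)
      while (2 * prod(sizes) > guard && max(sizes) > 2) {
        t_big <- parents[which.max(sizes)]
        tb <- tables[[t_big]]
        keep <- order(-tb$values, tb$keys)[seq_len(ceiling(length(tb$values) / 2))]
        tables[[t_big]] <- list(keys = tb$keys[keep], values = tb$values[keep],
                                idx = tb$idx[keep],
                                bits = tb$bits[keep, , drop = FALSE],
                                boundary = tb$boundary, nodes = tb$nodes)
        sizes <- vapply(parents, function(t) length(tables[[t]]$values), integer(1))
        pruned_any <- TRUE
      }
    }

    M <- as.integer(2 * prod(sizes))
    y <- rep_len(c(0L, 1L), M)
    pidx <- matrix(0L, M, length(parents))
    if (length(parents)) {
      block <- 2L
      for (t in seq_along(parents)) {
        pidx[, t] <- rep(rep(seq_len(sizes[t]), each = block),
                         length.out = M)
        block <- block * sizes[t]
      }
    }
    val <- node_pot[v, y + 1L]
    for (t in seq_along(parents)) {
      val <- val + tables[[parents[t]]]$values[pidx[, t]]
    }
    for (u in hnb) {
      t <- match(comp_of[u], parents)
      yu <- tables[[parents[t]]]$bits[pidx[, t],
                                      match(u, tables[[parents[t]]]$boundary)]
      p <- if (v < u) y + 2L * yu else yu + 2L * y
      k <- edge_idx[v, u]
      val <- val + edge_pot[k, p + 1L]
    }

    new_nodes <- c(v, unlist(lapply(parents, function(t) tables[[t]]$nodes)))
    bnd_cand <- sort(c(v, unlist(lapply(parents, function(t) tables[[t]]$boundary))))
    bnd <- bnd_cand[vapply(bnd_cand, function(u) any(!processed[adj[[u]]]),
                           logical(1))]
    newkey <- numeric(M)
    jb <- matrix(0L, M, length(bnd))
    for (pos in seq_along(bnd)) {
      u <- bnd[pos]
      b <- if (u == v) y else {
        t <- match(comp_of[u], parents)
        tables[[parents[t]]]$bits[pidx[, t],
                                  match(u, tables[[parents[t]]]$boundary)]
      }
      jb[, pos] <- b
      newkey <- newkey + b * 2^(pos - 1)
    }

    next_id <- next_id + 1L
    if (mode == "max") {
      o <- order(newkey, -val)
      sel <- o[!duplicated(newkey[o])]
      keys_new <- newkey[sel]
      values_new <- val[sel]
      bits_new <- jb[sel, , drop = FALSE]
      bp_y <- y[sel]
      bp_parent <- pidx[sel, , drop = FALSE]
      for (t in seq_along(parents)) {
        bp_parent[, t] <- tables[[parents[t]]]$idx[bp_parent[, t]]
      }
      if (bounded && length(values_new) > beam$max_entries) {
        keep <- .prune_indices(values_new, keys_new, beam)
        keys_new <- keys_new[keep]; values_new <- values_new[keep]
        bits_new <- bits_new[keep, , drop = FALSE]
        bp_y <- bp_y[keep]; bp_parent <- bp_parent[keep, , drop = FALSE]
        pruned_any <- TRUE
      }
      records[[step]] <- list(comp = next_id, v = v, parents = parents,
                              bp_y = bp_y, bp_parent = bp_parent)
    } else {
      o <- order(newkey)
      ko <- newkey[o]
      grp_start <- which(!duplicated(ko))
      keys_new <- ko[grp_start]
      bits_new <- jb[o[grp_start], , drop = FALSE]
      gi <- integer(M)
      gi[o] <- findInterval(seq_len(M), grp_start)
      values_new <- vapply(seq_along(keys_new), function(g)
        .logsumexp(val[gi == g]), 0)
      records[[step]] <- list(comp = next_id, v = v, parents = parents,
                              y = if (keep_grid) y,
                              pidx = if (keep_grid) pidx,
                              val = if (keep_grid) val,
                              gi = if (keep_grid) gi)
    }

    for (t in parents) tables[[t]] <- list(values = numeric(0))
    tables[[next_id]] <- list(keys = keys_new, values = values_new,
                              idx = seq_along(values_new), bits = bits_new,
                              boundary = bnd, nodes = new_nodes)
    comp_of[new_nodes] <- next_id
  }

  final <- sort(unique(comp_of))
  list(records = records, tables = tables, final = final, comp_of = comp_of,
       pruned = pruned_any)
}

.prune_indices <- function(values, keys, beam) {
  K <- length(values)
  budget <- beam$max_entries
  if (K <= 4096) {
    return(order(-values, keys)[seq_len(budget)])
  }
  discard <- 1 - budget / K
  samp <- values[sample.int(K, beam$sample_size, replace = TRUE)]
  perc <- unname(stats::quantile(samp, probs = discard, type = 1))
  keep <- which(values > perc)
  if (!length(keep)) keep <- which.max(values)
  keep
}

#' Prune a boundary table to a beam budget
#'
#' Applies the beam heuristic to a single Viterbi table: a table already
#' within budget is untouched; small tables are cut by exact order statistics;
#' large tables estimate the discard percentile from a with-replacement
#' sample of their values and retain entries strictly exceeding it (never
#' fewer than one).
#'
#' @param keys,values Parallel vectors: packed boundary assignments and their
#'   Viterbi values.
#' @param beam A bounded [beam_config()].
#' @return List with pruned `keys`, `values` and the retained `idx`.
#' @export
prune_table <- function(keys, values, beam) {
  stopifnot(inherits(beam, "beam_config"), is.finite(beam$max_entries))
  if (length(values) <= beam$max_entries) {
    return(list(keys = keys, values = values, idx = seq_along(values)))
  }
  keep <- .prune_indices(values, keys, beam)
  list(keys = keys[keep], values = values[keep], idx = keep)
}

.edge_structures <- function(graph) {
  n <- n_positions(graph)
  ev <- as.matrix(graph$edges[, c("i", "j")])
  edge_idx <- matrix(0L, n, n)
  if (nrow(ev)) {
    edge_idx[ev] <- seq_len(nrow(ev))
    edge_idx[ev[, c(2, 1), drop = FALSE]] <- seq_len(nrow(ev))
  }
  edge_idx
}

#' MAP decoding by the generalized Viterbi algorithm
#'
#' Computes a maximum-a-posteriori label assignment of the pCRF by dynamic
#' programming over an elimination order: the processed positions form a
#' history set whose connected components carry Viterbi tables indexed by the
#' label assignments of their boundary (positions with an edge to an
#' unprocessed node). With an unlimited beam the result is the exact MAP
#' assignment; with a bounded beam the returned score is a lower bound on the
#' MAP score and the assignment is consistent with its reported score. Ties
#' are broken deterministically, preferring N labels.
#'
#' @param graph A `surface_graph`.
#' @param potentials A `potential_table` from [build_potentials()].
#' @param beam A [beam_config()]; default unlimited (exact).
#' @param order Optional custom elimination order; default from
#'   [elimination_order()].
#' @return A `pcrf_decode`: list with `labels` (character over `{"I","N"}`),
#'   `score`, `exact` (no pruning occurred), `order`.
#' @export
viterbi_decode <- function(graph, potentials, beam = beam_config(),
                           order = NULL) {
  n <- n_positions(graph)
  stopifnot(nrow(potentials$node) == n)
  if (is.null(order)) order <- elimination_order(graph)$order
  adj <- .adjacency(graph)
  res <- .run_pass(n, adj, potentials$node, potentials$edge,
                   .edge_structures(graph), order, mode = "max", beam = beam)
  score <- 0
  sel <- new.env(parent = emptyenv())
  for (t in res$final) {
    stopifnot(length(res$tables[[t]]$values) == 1L)
    score <- score + res$tables[[t]]$values[1]
    assign(as.character(t), 1L, envir = sel)
  }
  labels <- integer(n)
  for (step in rev(seq_along(order))) {
    rec <- res$records[[step]]
    r <- get(as.character(rec$comp), envir = sel)
    labels[rec$v] <- rec$bp_y[r]
    for (t in seq_along(rec$parents)) {
      assign(as.character(rec$parents[t]), rec$bp_parent[r, t], envir = sel)
    }
  }
  structure(list(labels = .int2lab(labels), score = score,
                 exact = !res$pruned, order = order),
            class = "pcrf_decode")
}

#' @export
print.pcrf_decode <- function(x, ...) {
  cat("<pcrf_decode> score ", format(x$score), ", ",
      sum(x$labels == "I"), "/", length(x$labels), " positions labeled I",
      if (!x$exact) " (beam-pruned)", "\n", sep = "")
  invisible(x)
}

#' Forward pass: log partition function and sampling record
#'
#' The forward analogue of the generalized Viterbi pass: potentials are
#' exponentiated, maxima become sums, and all arithmetic is carried out in
#' log space with log-sum-exp. Before the pass the elimination order is
#' augmented with dummy nodes (zero node and edge potentials, a single edge
#' to the augmented position) for every order index whose node would leave
#' the boundary immediately, so that every stage remains sampleable; the
#' reported `log_Z` removes the dummies' known contribution and equals the
#' log of the exact normalization factor. Bounded beams are refused because
#' posterior sampling requires exact tables.
#'
#' @inheritParams viterbi_decode
#' @param augment Insert dummy nodes (default `TRUE`).
#' @param keep_grid Keep per-stage joint tables needed by
#'   [sample_posterior()] (default `TRUE`).
#' @param beam Must be unlimited unless `force = TRUE`.
#' @param force Allow a bounded beam (the resulting `log_Z` is approximate
#'   and the record cannot be sampled from).
#' @return A `pcrf_forward`: list with `log_Z`, the stage records, the
#'   augmented order and graph bookkeeping, and the input potentials.
#' @export
forward_pass <- function(graph, potentials, order = NULL,
                         beam = beam_config(), augment = TRUE,
                         keep_grid = TRUE, force = FALSE) {
  if (is.finite(beam$max_entries) && !force) {
    stop("forward_pass with a bounded beam is refused: sampling correctness ",
         "requires exact tables (use force = TRUE for an approximate log Z)")
  }
  n <- n_positions(graph)
  stopifnot(nrow(potentials$node) == n)
  if (is.null(order)) order <- elimination_order(graph)$order
  adj <- .adjacency(graph)
  node_pot <- potentials$node
  edge_pot <- potentials$edge
  edge_idx <- .edge_structures(graph)
  n_aug <- n
  aug_order <- order
  if (augment) {
    # stages whose node has no unprocessed neighbour the moment it is added
    processed <- logical(n)
    insert_after <- integer(0)
    for (s in seq_along(order)) {
      processed[order[s]] <- TRUE
      if (s < length(order) && !any(!processed[adj[[order[s]]]])) {
        insert_after <- c(insert_after, s)
      }
    }
    if (length(insert_after)) {
      m0 <- nrow(edge_pot)
      edge_idx <- rbind(cbind(edge_idx, matrix(0L, n, length(insert_after))),
                        matrix(0L, length(insert_after), n + length(insert_after)))
      new_order <- integer(0)
      for (s in seq_along(order)) {
        new_order <- c(new_order, order[s])
        if (s %in% insert_after) {
          n_aug <- n_aug + 1L
          adj[[order[s]]] <- c(adj[[order[s]]], n_aug)
          adj[[n_aug]] <- order[s]
          m0 <- m0 + 1L
          edge_idx[order[s], n_aug] <- m0
          edge_idx[n_aug, order[s]] <- m0
          edge_pot <- rbind(edge_pot, rep(0, 4))
          new_order <- c(new_order, n_aug)
        }
      }
      aug_order <- new_order
      node_pot <- rbind(node_pot, matrix(0, n_aug - n, 2))
    }
  }
  res <- .run_pass(n_aug, adj, node_pot, edge_pot, edge_idx, aug_order,
                   mode = "sum", beam = beam, keep_grid = keep_grid)
  log_z <- sum(vapply(res$final, function(t) res$tables[[t]]$values[1], 0)) -
    (n_aug - n) * log(2)
  structure(list(log_Z = log_z, records = res$records, final = res$final,
                 order = aug_order, n = n, n_aug = n_aug,
                 exact = !res$pruned, keep_grid = keep_grid,
                 graph = graph, potentials = potentials),
            class = "pcrf_forward")
}

#' @export
print.pcrf_forward <- function(x, ...) {
  cat("<pcrf_forward> log Z =", format(x$log_Z), "over", x$n, "positions",
      if (x$n_aug > x$n) paste0("(+", x$n_aug - x$n, " dummy)"), "\n")
  invisible(x)
}

#' Posterior sampling by a random backward walk
#'
#' Draws i.i.d. assignments from the pCRF posterior `P(y | x)` by walking the
#' forward record backwards: at every stage, conditional on the already-drawn
#' assignment of the new boundary, a joint configuration of the stage node
#' and the retired boundary positions is drawn with probability proportional
#' to its forward contribution. Dummy positions are discarded.
#'
#' @param forward A `pcrf_forward` from an exact (unpruned) pass with
#'   `keep_grid = TRUE`.
#' @param n_samples Number of assignments to draw.
#' @param seed Optional integer seed.
#' @return An `n_samples` x `n` integer matrix (I = 1, N = 0).
#' @export
sample_posterior <- function(forward, n_samples, seed = NULL) {
  stopifnot(inherits(forward, "pcrf_forward"))
  if (!forward$exact) stop("cannot sample from a pruned forward record")
  if (!forward$keep_grid) stop("forward record was built with keep_grid = FALSE")
  if (!is.null(seed)) set.seed(seed)
  ns <- as.integer(n_samples)
  labels <- matrix(NA_integer_, ns, forward$n_aug)
  chosen <- new.env(parent = emptyenv())
  for (t in forward$final) assign(as.character(t), rep(1L, ns), envir = chosen)
  for (step in rev(seq_along(forward$order))) {
    rec <- forward$records[[step]]
    g_s <- get(as.character(rec$comp), envir = chosen)
    row_s <- integer(ns)
    for (g in unique(g_s)) {
      in_g <- which(g_s == g)
      rows <- which(rec$gi == g)
      if (length(rows) == 1L) {
        row_s[in_g] <- rows
      } else {
        w <- rec$val[rows]
        p <- exp(w - .logsumexp(w))
        row_s[in_g] <- rows[sample.int(length(rows), length(in_g),
                                       replace = TRUE, prob = p)]
      }
    }
    labels[, rec$v] <- rec$y[row_s]
    for (t in seq_along(rec$parents)) {
      assign(as.character(rec$parents[t]), rec$pidx[row_s, t], envir = chosen)
    }
  }
  labels[, seq_len(forward$n), drop = FALSE]
}

#' Posterior marginals of the interface label
#'
#' Per-position posterior probability `P(y_i = I | x)`. For small graphs
#' (`n <= 16`) the exact value is computed by enumeration; otherwise the
#' marginals are estimated from posterior samples, with the binomial standard
#' error reported.
#'
#' @param forward A `pcrf_forward`.
#' @param method `"auto"`, `"exact"` or `"sampling"`.
#' @param n_samples Sample count for the sampling path.
#' @param seed Optional seed for the sampling path.
#' @return A tibble with `index`, `p_I`, and `se` (0 on the exact path).
#' @export
posterior_marginals <- function(forward, method = c("auto", "exact", "sampling"),
                                n_samples = 10000L, seed = NULL) {
  method <- match.arg(method)
  n <- forward$n
  if (method == "auto") method <- if (n <= 16) "exact" else "sampling"
  if (method == "exact") {
    if (n > 20) stop("exact marginals require n <= 20")
    dist <- conditional_distribution_bruteforce(forward$potentials)
    Y <- .keys_to_matrix(dist$key, n)
    p <- as.numeric(crossprod(Y, dist$prob))
    return(tibble::tibble(index = seq_len(n), p_I = p, se = 0))
  }
  s <- sample_posterior(forward, n_samples, seed = seed)
  p <- colMeans(s)
  tibble::tibble(index = seq_len(n), p_I = p,
                 se = sqrt(p * (1 - p) / nrow(s)))
}
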