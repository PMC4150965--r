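#' Quantile bins for score characteristics
#'
#' Characteristics are discretised into `gamma` bins whose inner boundaries
#' are the `iota/gamma`-quantiles (`iota = 1..gamma-1`) of the characteristic's
#' empirical distribution on non-interface training residues. Quantiles are
#' type 1 (inverse empirical CDF), so boundaries are observed values and the
#' binning is exactly reproducible. Bin membership uses right-closed intervals
#' `(s_iota, s_{iota+1}]` with sentinels `s_0 = -Inf`, `s_gamma = +Inf`.
#' Duplicate boundaries are collapsed with a warning, reducing the effective
#' bin count.
#'
#' @param values Numeric characteristic values (typically restricted to
#'   non-interface residues).
#' @param gamma Number of bins, at least 2. Default 5.
#' @return A `bin_spec`: list with `boundaries` (strictly increasing) and
#'   `n_bins` (`length(boundaries) + 1`).
#' @export
fit_bins <- function(values, gamma = 5L) {
  stopifnot(gamma >= 2)
  values <- values[is.finite(values)]
  if (!length(values)) stop("cannot fit bins: no finite values")
  probs <- seq_len(gamma - 1) / gamma
  s <- unname(stats::quantile(values, probs = probs, type = 1))
  su <- unique(s)
  if (length(su) < length(s)) {
    warning("duplicate bin boundaries collapsed: effective bins ",
            length(su) + 1, " instead of ", gamma)
  }
  structure(list(boundaries = su, n_bins = length(su) + 1L),
            class = "bin_spec")
}

#' Zero-based bin index of characteristic values
#'
#' Returns `iota` in `0..n_bins-1` such that `x` lies in
#' `(s_iota, s_{iota+1}]` (boundaries are right-closed: a value equal to a
#' boundary falls in the lower bin).
#'
#' @param x Numeric values.
#' @param spec A `bin_spec`.
#' @return Integer vector of bin indices.
#' @export
bin_index <- function(x, spec) {
  findInterval(x, spec$boundaries, left.open = TRUE)
}

# --- characteristics ---------------------------------------------------------
# The model is deliberately score-only: one node characteristic and two
# (symmetric) edge characteristics of the observation vector zeta.
.characteristic_registry <- list(
  node = list(
    score = function(zeta, i) zeta[i]
  ),
  edge = list(
    mean = function(zeta, i, j) (zeta[i] + zeta[j]) / 2,
    absdiff = function(zeta, i, j) abs(zeta[i] - zeta[j])
  )
)

#' Construct a pCRF model object
#'
#' Bundles the binned base-feature weights of the pairwise CRF: the node
#' weight vector `alpha` (one block of `n_bins` entries per label, order N
#' then I), one edge weight vector per edge characteristic (one block per
#' label pair, order (N,N), (I,N), (N,I), (I,I)), the fitted bin
#' specifications, the correction factor `delta`, and the amplifier control
#' `eta3` used during training.
#'
#' @param bins Named list of `bin_spec`s: one entry per characteristic
#'   (default characteristics: `score`, `mean`, `absdiff`).
#' @param alpha Numeric node weights, length `2 * bins$score$n_bins`.
#' @param beta Named list of numeric edge weights, each of length
#'   `4 * n_bins` of its characteristic.
#' @param delta Correction factor `>= 1` (recorded; applied by [train_pcrf()]).
#' @param eta3 Amplifier control in `[0, 1]` (recorded).
#' @param node_characteristic,edge_characteristics Names into the
#'   characteristic registry.
#' @return A `pcrf_model`.
#' @export
pcrf_model <- function(bins, alpha, beta, delta = 1, eta3 = 0,
                       node_characteristic = "score",
                       edge_characteristics = c("mean", "absdiff")) {
  stopifnot(delta >= 1, eta3 >= 0, eta3 <= 1)
  stopifnot(length(alpha) == 2 * bins[[node_characteristic]]$n_bins)
  stopifnot(setequal(names(beta), edge_characteristics))
  for (ch in edge_characteristics) {
    stopifnot(length(beta[[ch]]) == 4 * bins[[ch]]$n_bins)
  }
  structure(list(bins = bins, alpha = as.numeric(alpha),
                 beta = lapply(beta, as.numeric),
                 delta = delta, eta3 = eta3,
                 node_characteristic = node_characteristic,
                 edge_characteristics = edge_characteristics,
                 version = "surfcrf-model-1"),
            class = "pcrf_model")
}

#' @export
print.pcrf_model <- function(x, ...) {
  cat("<pcrf_model> node characteristic:", x$node_characteristic,
      "| edge characteristics:", paste(x$edge_characteristics, collapse = ", "),
      "\n  bins:", paste(vapply(x$bins, `[[`, 1L, "n_bins"), collapse = "/"),
      "| delta:", x$delta, "| eta3:", x$eta3, "\n")
  invisible(x)
}

# indicator indices of the active base features --------------------------------
# node: y in {0 (N), 1 (I)}, bin b (0-based) -> y * B + b + 1
# edge: pair p = y_i + 2 * y_j in 0..3 (order NN, IN, NI, II), bin b ->
#       p * B + b + 1

#' Active base-feature indicator of a node or an edge
#'
#' For a given label (or label pair) and observation, exactly one indicator
#' per characteristic is active: the one matching the label and the bin of
#' the characteristic value. This returns the sparse indicator as the index
#' of the single active entry of the corresponding weight vector.
#'
#' @param model A `pcrf_model`.
#' @param zeta Observation vector of scores in `[0, 1]`.
#' @param i,j Position (and, for edges, second position).
#' @param y,yj Label(s), `"N"` or `"I"`.
#' @return For a node, a single index into `alpha`; for an edge, a named
#'   integer vector with one index per edge characteristic.
#' @export
base_feature_index <- function(model, zeta, i, y, j = NULL, yj = NULL) {
  yi <- .lab2int(y)
  if (is.null(j)) {
    B <- model$bins[[model$node_characteristic]]$n_bins
    C <- .characteristic_registry$node[[model$node_characteristic]](zeta, i)
    b <- bin_index(C, model$bins[[model$node_characteristic]])
    return(yi * B + b + 1L)
  }
  p <- yi + 2L * .lab2int(yj)
  out <- integer(0)
  for (ch in model$edge_characteristics) {
    B <- model$bins[[ch]]$n_bins
    D <- .characteristic_registry$edge[[ch]](zeta, i, j)
    b <- bin_index(D, model$bins[[ch]])
    out[ch] <- p * B + b + 1L
  }
  out
}

.lab2int <- function(y) {
  v <- ifelse(y == "I", 1L, ifelse(y == "N", 0L, NA_integer_))
  if (anyNA(v)) stop("labels must be 'I' or 'N'")
  v
}

.int2lab <- function(y) c("N", "I")[y + 1L]

#' Build the potential tables of a pCRF on an observation
#'
#' Evaluates every node pair `(Phi_i(N), Phi_i(I))` and every edge quadruplet
#' `(Phi(N,N), Phi(I,N), Phi(N,I), Phi(I,I))` as the sum of weighted active
#' base features, then multiplies each edge's `(I,I)` entry by `kappa`.
#' Sweeping `kappa` over `(0, Inf)` moves the decoder's operating point and
#' traces the enhancer's ROC curve; `kappa = 1` is the plain model.
#'
#' @param model A `pcrf_model`.
#' @param zeta Observation: numeric scores in `[0, 1]`, one per graph position.
#' @param graph A `surface_graph`.
#' @param kappa Positive scaling of the `(I,I)` edge potentials.
#' @return A `potential_table`: list with `node` (n x 2 matrix, columns
#'   `N`, `I`), `edge` (m x 4 matrix, columns `NN`, `IN`, `NI`, `II`) and
#'   `edges` (m x 2 integer matrix of endpoints, `i < j`).
#' @export
build_potentials <- function(model, zeta, graph, kappa = 1) {
  n <- n_positions(graph)
  stopifnot(length(zeta) == n, kappa > 0)
  if (any(zeta < 0 | zeta > 1)) stop("scores must lie in [0, 1]")
  nb <- model$bins[[model$node_characteristic]]
  B <- nb$n_bins
  Cv <- vapply(seq_len(n), function(i)
    .characteristic_registry$node[[model$node_characteristic]](zeta, i), 0)
  b <- bin_index(Cv, nb)
  node <- cbind(N = model$alpha[b + 1L], I = model$alpha[B + b + 1L])
  ev <- as.matrix(graph$edges[, c("i", "j")])
  m <- nrow(ev)
  edge <- matrix(0, m, 4, dimnames = list(NULL, c("NN", "IN", "NI", "II")))
  if (m > 0) {
    for (ch in model$edge_characteristics) {
      Bc <- model$bins[[ch]]$n_bins
      f <- .characteristic_registry$edge[[ch]]
      Dv <- vapply(seq_len(m), function(k) f(zeta, ev[k, 1], ev[k, 2]), 0)
      bc <- bin_index(Dv, model$bins[[ch]])
      for (p in 0:3) edge[, p + 1L] <- edge[, p + 1L] +
          model$beta[[ch]][p * Bc + bc + 1L]
    }
    edge[, "II"] <- kappa * edge[, "II"]
  }
  structure(list(node = node, edge = edge, edges = ev),
            class = "potential_table")
}

#' Score of a full label assignment
#'
#' The score of assignment `y` given the observation is the sum of its node
#' potentials plus the sum of its edge potentials; the pCRF's conditional
#' probability is `exp(score) / Z`.
#'
#' @param labels Character vector over `{"I","N"}` covering every position
#'   (or an integer 0/1 vector, N = 0).
#' @param potentials A `potential_table`.
#' @return A single numeric score.
#' @export
assignment_score <- function(labels, potentials) {
  y <- if (is.character(labels)) .lab2int(labels) else as.integer(labels)
  n <- nrow(potentials$node)
  if (length(y) != n || anyNA(y)) {
    stop("assignment must cover all ", n, " positions (use partial scores for subsets)")
  }
  s <- sum(potentials$node[cbind(seq_len(n), y + 1L)])
  if (nrow(potentials$edges) > 0) {
    p <- y[potentials$edges[, 1]] + 2L * y[potentials$edges[, 2]]
    s <- s + sum(potentials$edge[cbind(seq_len(nrow(potentials$edges)), p + 1L)])
  }
  s
}

#' Exact conditional distribution by enumeration
#'
#' Enumerates all `2^n` assignments and returns their scores and normalized
#' probabilities `exp(score) / Z`. Intended for testing and for exact
#' posterior quantities at small `n`; refuses `n > 20` (use the forward pass
#' instead).
#'
#' @param potentials A `potential_table`.
#' @return A tibble with `key` (packed assignment: bit `k-1` is position `k`,
#'   I = 1), `labels` (string like `"NIN"`), `score`, `prob`.
#' @export
conditional_distribution_bruteforce <- function(potentials) {
  n <- nrow(potentials$node)
  if (n > 20) stop("n = ", n, " too large for enumeration; use forward_pass()")
  keys <- 0:(2^n - 1)
  Y <- .keys_to_matrix(keys, n)
  scores <- vapply(seq_along(keys), function(r)
    assignment_score(Y[r, ], potentials), 0)
  lz <- .logsumexp(scores)
  tibble::tibble(
    key = keys,
    labels = apply(Y, 1, function(y) paste(.int2lab(y), collapse = "")),
    score = scores,
    prob = exp(scores - lz))
}

# rows = assignments, columns = positions; bit k-1 of key is position k
.keys_to_matrix <- function(keys, n) {
  out <- vapply(seq_len(n), function(k) bitwAnd(bitwShiftR(keys, k - 1L), 1L),
                integer(length(keys)))
  if (length(keys) == 1L) out <- matrix(out, nrow = 1L)
  out
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
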