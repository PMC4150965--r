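#' Pooled label statistics of a training set
#'
#' Counts, pooled over all training instances, the interface positions
#' (`nu_I`), non-interface positions (`nu_N`), interface-interface edges
#' (`nu_II`) and non-interface-non-interface edges (`nu_NN`). Mixed-label
#' edges are counted in neither edge class.
#'
#' @param instances List of training instances; each is a list with `graph`
#'   (a `surface_graph`), `scores` (numeric) and `labels` (character over
#'   `{"I","N"}`).
#' @return A list with `nu_I`, `nu_N`, `nu_II`, `nu_NN`.
#' @export
count_label_statistics <- function(instances) {
  stopifnot(length(instances) >= 1)
  nu <- c(nu_I = 0L, nu_N = 0L, nu_II = 0L, nu_NN = 0L)
  for (ins in instances) {
    y <- .lab2int(ins$labels)
    stopifnot(length(y) == n_positions(ins$graph))
    nu["nu_I"] <- nu["nu_I"] + sum(y == 1L)
    nu["nu_N"] <- nu["nu_N"] + sum(y == 0L)
    ev <- as.matrix(ins$graph$edges[, c("i", "j")])
    if (nrow(ev)) {
      s <- y[ev[, 1]] + y[ev[, 2]]
      nu["nu_II"] <- nu["nu_II"] + sum(s == 2L)
      nu["nu_NN"] <- nu["nu_NN"] + sum(s == 0L)
    }
  }
  if (nu["nu_I"] == 0L || nu["nu_N"] == 0L) {
    stop("both node label classes must occur in the training set")
  }
  as.list(nu)
}

#' Class-imbalance amplifier weights
#'
#' Training data are heavily imbalanced towards non-interface residues. The
#' influence of the positive examples is amplified by per-class
#' multiplicative weights: an interface position receives `(nu_N / nu_I)^eta3`
#' and an interface-interface edge `(nu_NN / nu_II)^eta3`; everything else
#' (including mixed-label edges) receives 1. `eta3 = 0` switches
#' amplification off, `eta3 = 1` fully rebalances the classes.
#'
#' @param kind `"node"` or `"edge"`.
#' @param label `"I"` or `"N"` for nodes; `"II"`, `"NN"`, `"IN"` or `"NI"`
#'   for edges.
#' @param counts Output of [count_label_statistics()].
#' @param eta3 Amplifier control in `[0, 1]`.
#' @return A positive scalar.
#' @export
amplifier_weight <- function(kind = c("node", "edge"), label, counts, eta3) {
  kind <- match.arg(kind)
  stopifnot(eta3 >= 0, eta3 <= 1)
  if (kind == "node") {
    if (label == "N") return(1)
    stopifnot(label == "I")
    if (counts$nu_I == 0 && eta3 > 0) stop("nu_I = 0: node amplifier undefined")
    return((counts$nu_N / counts$nu_I)^eta3)
  }
  if (label != "II") return(1)
  if (counts$nu_II == 0 && eta3 > 0) stop("nu_II = 0: edge amplifier undefined")
  (counts$nu_NN / counts$nu_II)^eta3
}

#' Training configuration
#'
#' @param eta3 Amplifier control in `[0, 1]`; default 1 (full rebalancing).
#' @param delta Correction factor `>= 1` multiplying the equal-label edge
#'   base-feature weights after optimization; default 1.2 (best between 1.15
#'   and 1.25).
#' @param gamma Bin count per characteristic; default 5.
#' @param maxit,grad_tol Optimizer budget and gradient-norm tolerance.
#' @param l2 Optional L2 penalty strength (0 = none, the default).
#' @return A `train_config`.
#' @export
train_config <- function(eta3 = 1, delta = 1.2, gamma = 5L,
                         maxit = 500L, grad_tol = 1e-6, l2 = 0) {
  stopifnot(eta3 >= 0, eta3 <= 1, delta >= 1, gamma >= 2, l2 >= 0)
  structure(list(eta3 = eta3, delta = delta, gamma = as.integer(gamma),
                 maxit = as.integer(maxit), grad_tol = grad_tol, l2 = l2),
            class = "train_config")
}

# Precompute, pooled over instances, everything the piecewise objective needs:
# active feature indices per node/edge under each label(-pair), true labels,
# and amplifier weights. Bins must already be fitted.
.training_design <- function(instances, bins, counts, eta3,
                             node_characteristic = "score",
                             edge_characteristics = c("mean", "absdiff")) {
  Bn <- bins[[node_characteristic]]$n_bins
  nb_all <- integer(0); ny_all <- integer(0)
  eb_all <- list(); ep_all <- integer(0)
  for (ch in edge_characteristics) eb_all[[ch]] <- integer(0)
  for (ins in instances) {
    zeta <- ins$scores
    y <- .lab2int(ins$labels)
    n <- length(zeta)
    Cv <- vapply(seq_len(n), function(i)
      .characteristic_registry$node[[node_characteristic]](zeta, i), 0)
    nb_all <- c(nb_all, bin_index(Cv, bins[[node_characteristic]]))
    ny_all <- c(ny_all, y)
    ev <- as.matrix(ins$graph$edges[, c("i", "j")])
    if (nrow(ev)) {
      for (ch in edge_characteristics) {
        f <- .characteristic_registry$edge[[ch]]
        Dv <- vapply(seq_len(nrow(ev)), function(k) f(zeta, ev[k, 1], ev[k, 2]), 0)
        eb_all[[ch]] <- c(eb_all[[ch]], bin_index(Dv, bins[[ch]]))
      }
      ep_all <- c(ep_all, y[ev[, 1]] + 2L * y[ev[, 2]])
    }
  }
  amp_node <- c(1, amplifier_weight("node", "I", counts, eta3))        # by y+1
  amp_edge <- c(1, 1, 1, amplifier_weight("edge", "II", counts, eta3)) # by p+1
  Be <- vapply(edge_characteristics, function(ch) bins[[ch]]$n_bins,
               integer(1))
  # index-by-bin splits: make the gradient's indicator sums O(data) per call
  node_split <- split(seq_along(nb_all), factor(nb_all, levels = 0:(Bn - 1)))
  edge_split <- lapply(edge_characteristics, function(ch)
    split(seq_along(eb_all[[ch]]), factor(eb_all[[ch]], levels = 0:(Be[[ch]] - 1))))
  names(edge_split) <- edge_characteristics
  list(Bn = Bn, node_bin = nb_all, node_y = ny_all,
       edge_bin = eb_all, edge_p = ep_all,
       amp_node = amp_node, amp_edge = amp_edge,
       node_characteristic = node_characteristic,
       edge_characteristics = edge_characteristics,
       Be = Be, node_split = node_split, edge_split = edge_split)
}

# Split a flat parameter vector into alpha and per-characteristic beta blocks.
.split_theta <- function(theta, design) {
  na <- 2L * design$Bn
  alpha <- theta[seq_len(na)]
  beta <- list(); off <- na
  for (ch in design$edge_characteristics) {
    nb <- 4L * design$Be[[ch]]
    beta[[ch]] <- theta[off + seq_len(nb)]
    off <- off + nb
  }
  list(alpha = alpha, beta = beta)
}

#' Piecewise log-likelihood objective and its gradient
#'
#' Training with the true partition function is intractable on loopy graphs,
#' so node and edge labels are disentangled: the normalization factorizes
#' over "non-coherent" labelings into a product of independent local node and
#' edge normalizers. The objective is the sum, over pooled nodes and edges,
#' of the amplified local log-likelihood
#' `a(y) * (Phi(y) - log sum_y' exp(Phi(y')))`: the amplifier
#' ([amplifier_weight()]) multiplies the entire local term of its example,
#' so an interface node (or interface-interface edge) counts as `a(y)`
#' training examples. The objective is evaluated with its analytic gradient.
#'
#' @param theta Flat parameter vector: `alpha` followed by each edge
#'   characteristic's `beta` block.
#' @param design Internal pooled design (built by [train_pcrf()]); exposed
#'   for testing through this function's `instances` interface.
#' @param instances,bins,counts,eta3 Alternative entry: provide the training
#'   instances plus fitted bins; the design is built on the fly.
#' @param l2 Optional L2 penalty strength.
#' @return List with `value` and `gradient` (same length as `theta`).
#' @export
piecewise_objective <- function(theta, design = NULL, instances = NULL,
                                bins = NULL, counts = NULL, eta3 = 0, l2 = 0) {
  if (is.null(design)) {
    stopifnot(!is.null(instances), !is.null(bins))
    if (is.null(counts)) counts <- count_label_statistics(instances)
    design <- .training_design(instances, bins, counts, eta3)
  }
  th <- .split_theta(theta, design)
  Bn <- design$Bn
  grad <- numeric(length(theta))

  # nodes: Phi(y) = alpha[y*Bn + bin + 1]; the amplifier weights the whole
  # local log-likelihood term of its example
  b <- design$node_bin
  phiN <- th$alpha[b + 1L]
  phiI <- th$alpha[Bn + b + 1L]
  mx <- pmax(phiN, phiI)
  lZ <- mx + log(exp(phiN - mx) + exp(phiI - mx))
  datum <- ifelse(design$node_y == 1L, phiI, phiN)
  w <- design$amp_node[design$node_y + 1L]
  value <- sum(w * (datum - lZ))
  pN <- exp(phiN - lZ); pI <- exp(phiI - lZ)
  gN <- w * ((design$node_y == 0L) - pN)
  gI <- w * ((design$node_y == 1L) - pI)
  grad[seq_len(2L * Bn)] <-
    c(vapply(design$node_split, function(ii) sum(gN[ii]), 0),
      vapply(design$node_split, function(ii) sum(gI[ii]), 0))

  # edges: Phi(p) = sum over characteristics of beta_ch[p*B + bin + 1]
  if (length(design$edge_p)) {
    m <- length(design$edge_p)
    phi <- matrix(0, m, 4)
    for (ch in design$edge_characteristics) {
      Bc <- design$Be[[ch]]
      bb <- design$edge_bin[[ch]]
      for (p in 0:3) phi[, p + 1L] <- phi[, p + 1L] + th$beta[[ch]][p * Bc + bb + 1L]
    }
    mx <- apply(phi, 1, max)
    lZ <- mx + log(rowSums(exp(phi - mx)))
    datum <- phi[cbind(seq_len(m), design$edge_p + 1L)]
    we <- design$amp_edge[design$edge_p + 1L]
    value <- value + sum(we * (datum - lZ))
    pr <- exp(phi - lZ)
    ind <- matrix(0, m, 4)
    ind[cbind(seq_len(m), design$edge_p + 1L)] <- 1
    gmat <- we * (ind - pr)
    off <- 2L * Bn
    for (ch in design$edge_characteristics) {
      Bc <- design$Be[[ch]]
      spl <- design$edge_split[[ch]]
      for (p in 0:3) {
        gp <- gmat[, p + 1L]
        grad[off + p * Bc + seq_len(Bc)] <-
          vapply(spl, function(ii) sum(gp[ii]), 0)
      }
      off <- off + 4L * Bc
    }
  }
  if (l2 > 0) {
    value <- value - l2 * sum(theta^2) / 2
    grad <- grad - l2 * theta
  }
  list(value = value, gradient = grad)
}

#' Train a pCRF by piecewise likelihood maximization
#'
#' Fits the score bins on the non-interface training residues (node
#' characteristic on non-interface positions, edge characteristics on
#' non-interface-non-interface edges), counts the amplifier statistics,
#' maximizes the piecewise objective from a zero initialization with a
#' quasi-Newton method (L-BFGS), and finally multiplies the weights of the
#' equal-label edge base features (`(N,N)` and `(I,I)` indicators) by the
#' correction factor `delta`, additionally penalizing a change of
#' classification along an edge.
#'
#' @param instances Training instances (list of `graph`/`scores`/`labels`
#'   lists, see [count_label_statistics()]).
#' @param config A [train_config()].
#' @return A fitted `pcrf_model` (with `eta3` and `delta` recorded).
#' @export
train_pcrf <- function(instances, config = train_config()) {
  stopifnot(inherits(config, "train_config"), length(instances) >= 1)
  counts <- count_label_statistics(instances)
  bins <- fit_training_bins(instances, gamma = config$gamma)
  design <- .training_design(instances, bins, counts, config$eta3)
  npar <- 2L * design$Bn + sum(4L * design$Be)
  # optim calls fn and gr at the same point back to back: evaluate once
  cache <- list(theta = NULL, res = NULL)
  eval_at <- function(th) {
    if (is.null(cache$theta) || !identical(th, cache$theta)) {
      cache$theta <<- th
      cache$res <<- piecewise_objective(th, design, l2 = config$l2)
    }
    cache$res
  }
  fit <- stats::optim(rep(0, npar),
                      function(th) -eval_at(th)$value,
                      function(th) -eval_at(th)$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = config$maxit,
                                     pgtol = config$grad_tol, factr = 1e7))
  if (fit$convergence != 0) {
    warning("optimizer did not fully converge (code ", fit$convergence,
            "): ", fit$message, "; returning best iterate")
  }
  th <- .split_theta(fit$par, design)
  # delta correction: boost the equal-label ((N,N) and (I,I)) edge indicators
  for (ch in design$edge_characteristics) {
    Bc <- design$Be[[ch]]
    eq <- c(0L * Bc + seq_len(Bc), 3L * Bc + seq_len(Bc))
    th$beta[[ch]][eq] <- config$delta * th$beta[[ch]][eq]
  }
  pcrf_model(bins = bins, alpha = th$alpha, beta = th$beta,
             delta = config$delta, eta3 = config$eta3)
}

#' Fit the characteristic bins on non-interface training material
#'
#' The node characteristic's bins are fitted on the scores of non-interface
#' positions; each edge characteristic's bins on the values of edges whose
#' endpoints are both non-interface (falling back to all edges if no such
#' edge exists).
#'
#' @inheritParams train_pcrf
#' @param gamma Bin count.
#' @return Named list of `bin_spec`s (`score`, `mean`, `absdiff`).
#' @export
fit_training_bins <- function(instances, gamma = 5L,
                              node_characteristic = "score",
                              edge_characteristics = c("mean", "absdiff")) {
  node_vals <- numeric(0)
  edge_vals <- stats::setNames(
    rep(list(numeric(0)), length(edge_characteristics)), edge_characteristics)
  edge_vals_all <- edge_vals
  for (ins in instances) {
    y <- .lab2int(ins$labels)
    zeta <- ins$scores
    node_vals <- c(node_vals, vapply(which(y == 0L), function(i)
      .characteristic_registry$node[[node_characteristic]](zeta, i), 0))
    ev <- as.matrix(ins$graph$edges[, c("i", "j")])
    if (nrow(ev)) {
      nn <- y[ev[, 1]] == 0L & y[ev[, 2]] == 0L
      for (ch in edge_characteristics) {
        f <- .characteristic_registry$edge[[ch]]
        vals <- vapply(seq_len(nrow(ev)), function(k) f(zeta, ev[k, 1], ev[k, 2]), 0)
        edge_vals[[ch]] <- c(edge_vals[[ch]], vals[nn])
        edge_vals_all[[ch]] <- c(edge_vals_all[[ch]], vals)
      }
    }
  }
  if (!length(node_vals)) stop("no non-interface positions to fit bins on")
  bins <- list()
  bins[[node_characteristic]] <- fit_bins(node_vals, gamma)
  for (ch in edge_characteristics) {
    v <- if (length(edge_vals[[ch]])) edge_vals[[ch]] else edge_vals_all[[ch]]
    bins[[ch]] <- fit_bins(v, gamma)
  }
  bins
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy the weights of a fitted pCRF
#'
#' One row per base feature: the characteristic, the label (or label pair),
#' the bin, its interval, and the weight.
#'
#' @param x A `pcrf_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pcrf_model <- function(x, ...) {
  rows <- list()
  bnd <- function(spec) {
    lo <- c(-Inf, spec$boundaries); hi <- c(spec$boundaries, Inf)
    sprintf("(%s, %s]", format(lo, digits = 4), format(hi, digits = 4))
  }
  Bn <- x$bins[[x$node_characteristic]]$n_bins
  rows[[1]] <- tibble::tibble(
    characteristic = x$node_characteristic,
    label = rep(c("N", "I"), each = Bn),
    bin = rep(seq_len(Bn) - 1L, 2),
    interval = rep(bnd(x$bins[[x$node_characteristic]]), 2),
    weight = x$alpha)
  for (ch in x$edge_characteristics) {
    Bc <- x$bins[[ch]]$n_bins
    rows[[length(rows) + 1]] <- tibble::tibble(
      characteristic = ch,
      label = rep(c("NN", "IN", "NI", "II"), each = Bc),
      bin = rep(seq_len(Bc) - 1L, 4),
      interval = rep(bnd(x$bins[[ch]]), 4),
      weight = x$beta[[ch]])
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.pcrf_model
#' @export
glance.pcrf_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = length(x$alpha) + sum(lengths(x$beta)),
    gamma_node = x$bins[[x$node_characteristic]]$n_bins,
    delta = x$delta, eta3 = x$eta3, version = x$version)
}
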