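#' Beta shape parameters from mean and variance
#'
#' Moment matching: for mean `e` in (0,1) and variance `v` in
#' `(0, e(1-e))`, `a = e * (e(1-e)/v - 1)` and `b = (1-e) * (e(1-e)/v - 1)`
#' give the unique Beta distribution with those moments.
#'
#' @param e Mean in (0, 1).
#' @param v Variance; must satisfy `0 < v < e * (1 - e)`.
#' @return Named numeric vector `c(a, b)`.
#' @export
beta_params_from_moments <- function(e, v) {
  stopifnot(e > 0, e < 1)
  bound <- e * (1 - e)
  if (v <= 0 || v >= bound) {
    stop("infeasible variance ", v, ": a Beta with mean ", e,
         " requires 0 < v < e(1-e) = ", bound)
  }
  k <- bound / v - 1
  c(a = e * k, b = (1 - e) * k)
}

#' Class-conditional score distribution configuration
#'
#' The simulator assigns scores in (0, 1) to interface and non-interface
#' residues from two unimodal Beta distributions with fixed class means
#' `e_I > e_N` and variances scaled by the score precision `sigma`:
#' `v_class(sigma) = sigma^2 * s2_class`. The means are independent of
#' `sigma`; larger `sigma` means noisier (less precise) scores and more
#' class overlap.
#'
#' @param e_I,e_N Class means, `e_I > e_N`.
#' @param s2_I,s2_N Base class variances.
#' @param sigma Score precision scale; the study grid is
#'   `{0.8, 0.9, 1.0, 1.1, 1.2}`, any positive value is accepted.
#' @return A `beta_score_config` with the four Beta shapes.
#' @export
make_score_config <- function(e_I = 0.5, e_N = 0.3, s2_I = 0.02, s2_N = 0.02,
                              sigma = 1.0) {
  stopifnot(e_I > e_N, sigma > 0)
  shapes_I <- beta_params_from_moments(e_I, sigma^2 * s2_I)
  shapes_N <- beta_params_from_moments(e_N, sigma^2 * s2_N)
  structure(list(e_I = e_I, e_N = e_N, s2_I = s2_I, s2_N = s2_N,
                 sigma = sigma,
                 alpha_I = unname(shapes_I["a"]), beta_I = unname(shapes_I["b"]),
                 alpha_N = unname(shapes_N["a"]), beta_N = unname(shapes_N["b"])),
            class = "beta_score_config")
}

#' @export
print.beta_score_config <- function(x, ...) {
  cat(sprintf(paste0("<beta_score_config> sigma = %.2f | I ~ Beta(%.3f, %.3f)",
                     " (mean %.3f) | N ~ Beta(%.3f, %.3f) (mean %.3f)\n"),
              x$sigma, x$alpha_I, x$beta_I, x$e_I, x$alpha_N, x$beta_N, x$e_N))
  invisible(x)
}

#' Simulate class-conditional residue scores
#'
#' Independently draws a score for every position: interface positions from
#' `Beta(alpha_I, beta_I)`, non-interface positions from
#' `Beta(alpha_N, beta_N)`.
#'
#' @param labels Character vector over `{"I","N"}`.
#' @param config A [make_score_config()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric score vector in (0, 1), one per label.
#' @export
simulate_scores <- function(labels, config, seed = NULL) {
  stopifnot(inherits(config, "beta_score_config"))
  if (!is.null(seed)) set.seed(seed)
  y <- .lab2int(labels)
  out <- numeric(length(y))
  out[y == 1L] <- stats::rbeta(sum(y == 1L), config$alpha_I, config$beta_I)
  out[y == 0L] <- stats::rbeta(sum(y == 0L), config$alpha_N, config$beta_N)
  out
}

#' Synthetic protein-surface-like graph with an interface patch
#'
#' Stands in for real surfaces in pipeline tests and simulations: `n` points
#' are placed uniformly on the unit sphere, two points are joined when their
#' angular (chord) distance is below the radius calibrated to the requested
#' expected degree, and the interface is the spherical cap around a random
#' axis containing the requested fraction of points, so interface positions
#' form a connected patch. Generation is retried with fresh sub-seeds until
#' the graph is connected (at most 100 attempts).
#'
#' @param n Number of surface positions (at least 10).
#' @param expected_degree Target mean degree of the graph.
#' @param interface_fraction Fraction of positions labeled `I`, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list with `graph` (a `surface_graph`, convention tag `cgnk`)
#'   and `labels` (character vector).
#' @export
synthetic_surface <- function(n = 150, expected_degree = 8,
                              interface_fraction = 0.15, seed = 1) {
  stopifnot(n >= 10, interface_fraction >= 0, interface_fraction < 1)
  # a point's neighbourhood cap of angular radius phi holds a fraction
  # (1 - cos(phi)) / 2 of the sphere; calibrate to the expected degree
  frac <- expected_degree / (n - 1)
  stopifnot(frac < 1)
  chord <- sqrt(2 - 2 * (1 - 2 * frac))
  for (attempt in seq_len(100)) {
    set.seed(seed + 7919L * (attempt - 1L))
    z <- stats::rnorm(n * 3)
    xyz <- matrix(z, n, 3)
    xyz <- xyz / sqrt(rowSums(xyz^2))
    d <- as.matrix(stats::dist(xyz))
    adjm <- d < chord
    diag(adjm) <- FALSE
    if (any(rowSums(adjm) == 0)) next
    gi <- igraph::graph_from_adjacency_matrix(adjm, mode = "undirected")
    if (!igraph::is_connected(gi)) next
    # interface: spherical cap around a random axis holding the top fraction
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    proj <- as.numeric(xyz %*% axis)
    n_if <- round(interface_fraction * n)
    labels <- rep("N", n)
    if (n_if > 0) labels[order(proj, decreasing = TRUE)[seq_len(n_if)]] <- "I"
    if (n_if > 1 &&
        igraph::components(igraph::induced_subgraph(gi, which(labels == "I")))$no != 1) {
      next
    }
    idx <- which(upper.tri(adjm) & adjm, arr.ind = TRUE)
    nodes <- tibble::tibble(index = seq_len(n), chain = "A",
                            resno = seq_len(n), insert = "",
                            resid = "ALA", rasa = NA_real_,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    edges <- tibble::tibble(i = unname(idx[, 1]), j = unname(idx[, 2]),
                            distance = unname(d[idx])) |>
      dplyr::arrange(.data$i, .data$j)
    graph <- new_surface_graph(nodes, edges, "cgnk", chord)
    return(list(graph = graph, labels = labels))
  }
  stop("could not generate a connected synthetic surface in 100 attempts")
}

#' Simulate a full synthetic study instance set
#'
#' Generates `m` spherical surfaces with connected interface patches and
#' class-conditional Beta scores, the desk-scale stand-in for scored real
#' protein surfaces.
#'
#' @param m Number of instances.
#' @inheritParams synthetic_surface
#' @param config A [make_score_config()].
#' @param seed Integer master seed; instance `k` uses `seed + k` for its
#'   surface and `seed + 100000 + k` for its scores.
#' @return List of instances (`graph`, `labels`, `scores`).
#' @export
simulate_instances <- function(m, n = 150, expected_degree = 8,
                               interface_fraction = 0.15,
                               config = make_score_config(), seed = 1) {
  purrr::map(seq_len(m), function(k) {
    surf <- synthetic_surface(n, expected_degree, interface_fraction,
                              seed = seed + k)
    scores <- simulate_scores(surf$labels, config, seed = seed + 100000L + k)
    list(graph = surf$graph, labels = surf$labels, scores = scores)
  })
}
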