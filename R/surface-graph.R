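#' Surface residue selection by relative accessibility
#'
#' A residue belongs to the protein surface when its relative
#' solvent-accessible surface area is at least the convention's threshold:
#' 5% under the `planedimers` convention and 15% under `kl` and `cgnk`.
#' The comparison is inclusive ("at least").
#'
#' @param rasa A tibble as returned by [compute_rasa()] (must contain a
#'   `rasa` column).
#' @param convention One of `"planedimers"`, `"kl"`, `"cgnk"`.
#' @return The rows of `rasa` belonging to the surface.
#' @export
select_surface <- function(rasa, convention = c("planedimers", "kl", "cgnk")) {
  convention <- match.arg(convention)
  thr <- rasa_threshold(convention)
  out <- dplyr::filter(rasa, .data$rasa >= thr)
  if (nrow(out) == 0) {
    stop("no surface residues: all RASA values below the ", convention,
         " threshold of ", thr)
  }
  out
}

#' @rdname select_surface
#' @export
rasa_threshold <- function(convention = c("planedimers", "kl", "cgnk")) {
  convention <- match.arg(convention)
  if (convention == "planedimers") 0.05 else 0.15
}

#' Representative-carbon coordinates of residues
#'
#' Residue-residue distances are measured between "major carbon" atoms. The
#' default representative is the alpha carbon (CA), which exists in every
#' standard residue; CB is offered as an alternative (falling back to CA for
#' glycine). Residues missing the representative atom fall back to their first
#' heavy atom with a warning; residues with no heavy atoms are dropped with a
#' warning.
#'
#' @param structure A `bio3d` `pdb` object or PDB file path.
#' @param chain Optional chain restriction.
#' @param representative `"CA"` (default) or `"CB"`.
#' @return A tibble with `chain`, `resno`, `insert`, `resid`, `x`, `y`, `z`.
#' @export
representative_coords <- function(structure, chain = NULL,
                                  representative = c("CA", "CB")) {
  representative <- match.arg(representative)
  atoms <- .clean_atoms(structure, chain = chain)
  if (nrow(atoms) == 0) stop("no protein atoms found")
  pick <- function(df) {
    want <- representative
    if (want == "CB" && df$resid[1] == "GLY") want <- "CA"
    hit <- which(df$elety == want)
    if (!length(hit)) {
      hit <- which(df$elety == "CA")
      if (!length(hit)) hit <- 1L
      attr(df, "fallback") <- TRUE
    }
    df[hit[1], c("chain", "resno", "insert", "resid", "x", "y", "z")]
  }
  grp <- split(atoms, paste(atoms$chain, atoms$resno, atoms$insert))
  res <- purrr::map(grp, pick)
  n_fb <- sum(purrr::map_lgl(res, ~ isTRUE(attr(.x, "fallback"))))
  if (n_fb > 0) {
    warning(n_fb, " residue(s) missing the ", representative,
            " atom; using first heavy atom instead")
  }
  dplyr::bind_rows(res) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert) |>
    tibble::as_tibble()
}

#' Build the spatial neighborhood graph of surface residues
#'
#' Two surface residues of the same chain are joined by an undirected edge
#' when the Euclidean distance of their representative carbons is strictly
#' below the cutoff (default 6 Angstrom). Positions left with degree zero are
#' dropped with a warning, so the resulting graph has no isolated nodes.
#' Positions are renumbered 1..n in chain order after filtering; the mapping
#' back to PDB numbering is kept in the node table.
#'
#' @param nodes A tibble with one row per surface residue carrying at least
#'   `x`, `y`, `z`; typically a join of [representative_coords()] and
#'   [select_surface()] output, with `chain`, `resno`, `insert`, `resid`,
#'   `rasa` columns.
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @param convention Convention tag stored on the graph.
#' @return A `surface_graph`: a list with tibbles `nodes` (with 1-based
#'   `index`) and `edges` (`i`, `j`, `distance`, with `i < j`), plus the
#'   convention and cutoff.
#' @export
build_neighborhood_graph <- function(nodes, cutoff = 6,
                                     convention = c("planedimers", "kl", "cgnk")) {
  convention <- match.arg(convention)
  stopifnot(all(c("x", "y", "z") %in% names(nodes)))
  if (nrow(nodes) < 1) stop("no surface residues to build a graph from")
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d < cutoff
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  if (any(deg == 0)) {
    warning(sum(deg == 0), " isolated position(s) dropped (degree 0 at cutoff ",
            cutoff, " Angstrom)")
    keep <- which(deg > 0)
    if (!length(keep)) stop("all positions isolated; no graph remains")
    nodes <- nodes[keep, , drop = FALSE]
    d <- d[keep, keep, drop = FALSE]
    adj <- adj[keep, keep, drop = FALSE]
  }
  n <- nrow(nodes)
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- tibble::tibble(i = unname(idx[, 1]), j = unname(idx[, 2]),
                          distance = unname(d[idx]))
  edges <- dplyr::arrange(edges, .data$i, .data$j)
  nodes <- dplyr::mutate(nodes, index = seq_len(n), .before = 1)
  new_surface_graph(nodes, edges, convention, cutoff)
}

new_surface_graph <- function(nodes, edges, convention, cutoff) {
  g <- list(nodes = tibble::as_tibble(nodes),
            edges = tibble::as_tibble(edges),
            convention = convention, cutoff = cutoff)
  class(g) <- "surface_graph"
  validate_surface_graph(g)
}

validate_surface_graph <- function(g) {
  n <- nrow(g$nodes)
  stopifnot(n >= 1)
  if (nrow(g$edges)) {
    stopifnot(all(g$edges$i >= 1), all(g$edges$j <= n),
              all(g$edges$i < g$edges$j))
    key <- paste(g$edges$i, g$edges$j)
    stopifnot(!anyDuplicated(key))
    stopifnot(all(tabulate(c(g$edges$i, g$edges$j), n) > 0))
  }
  g
}

#' @export
print.surface_graph <- function(x, ...) {
  cat("<surface_graph> ", nrow(x$nodes), " positions, ", nrow(x$edges),
      " edges (", x$convention, " convention, cutoff ", x$cutoff,
      " Angstrom)\n", sep = "")
  invisible(x)
}

#' Number of positions of a surface graph
#' @param g A `surface_graph`.
#' @return Integer count of positions.
#' @export
n_positions <- function(g) nrow(g$nodes)

# adjacency list: integer vector of neighbours per position
.adjacency <- function(g) {
  n <- n_positions(g)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Reference interface labels from a complex structure
#'
#' Labels every surface position of `graph` as interface (`I`) or
#' non-interface (`N`) by a contact criterion against all partner chains of
#' the complex:
#' * `kl`: some heavy atom of the residue within 5 Angstrom (inclusive) of a
#'   partner-chain heavy atom;
#' * `planedimers`: van der Waals spheres within 0.5 Angstrom, i.e.
#'   `d - r1 - r2 <= 0.5` (inclusive);
#' * `cgnk`: `d < r1 + r2 + 0.5` (strict).
#'
#' @param structure The complex (a `bio3d` `pdb` object or path); must have at
#'   least two chains.
#' @param target_chain Chain whose surface is labeled.
#' @param graph The `surface_graph` of the target chain.
#' @param convention Contact convention; defaults to the graph's.
#' @return A character vector over `{"I","N"}`, one per graph position.
#' @export
derive_interface_labels <- function(structure, target_chain, graph,
                                    convention = NULL) {
  if (is.null(convention)) convention <- graph$convention
  convention <- match.arg(convention, c("planedimers", "kl", "cgnk"))
  atoms <- .clean_atoms(structure)
  partner <- atoms[atoms$chain != target_chain, , drop = FALSE]
  own <- atoms[atoms$chain == target_chain, , drop = FALSE]
  if (nrow(partner) == 0) {
    stop("no partner chain present: interface labels need a complex with >= 2 chains")
  }
  pxyz <- as.matrix(partner[, c("x", "y", "z")])
  pr <- .vdw_radius(partner$elesy)
  labels <- rep("N", n_positions(graph))
  for (k in seq_len(n_positions(graph))) {
    nd <- graph$nodes[k, ]
    ra <- own[own$resno == nd$resno & own$insert == .blank(nd$insert), ,
              drop = FALSE]
    if (nrow(ra) == 0) next
    axyz <- as.matrix(ra[, c("x", "y", "z")])
    ar <- .vdw_radius(ra$elesy)
    hit <- FALSE
    for (a in seq_len(nrow(axyz))) {
      dd <- sqrt(colSums((t(pxyz) - axyz[a, ])^2))
      hit <- switch(convention,
        kl = any(dd <= 5),
        planedimers = any(dd - ar[a] - pr <= 0.5),
        cgnk = any(dd < ar[a] + pr + 0.5))
      if (hit) break
    }
    if (hit) labels[k] <- "I"
  }
  labels
}

.blank <- function(x) ifelse(is.na(x) | x == "", "", x)

#' One-call surface graph construction from a structure
#'
#' Convenience pipeline: per-residue RASA, surface selection under the
#' convention, representative-carbon coordinates, and neighborhood graph.
#' Graphs are built per chain (the model describes one chain's surface).
#'
#' @inheritParams compute_rasa
#' @inheritParams build_neighborhood_graph
#' @param chain Chain identifier (required).
#' @param representative Passed to [representative_coords()].
#' @return A `surface_graph`.
#' @export
surface_graph_from_structure <- function(structure, chain,
                                         convention = c("planedimers", "kl", "cgnk"),
                                         cutoff = 6,
                                         representative = c("CA", "CB"),
                                         probe = 1.4, n_points = 960L) {
  convention <- match.arg(convention)
  if (is.character(structure)) structure <- bio3d::read.pdb(structure)
  ras <- compute_rasa(structure, chain = chain, probe = probe,
                      n_points = n_points)
  surf <- select_surface(ras, convention)
  coords <- representative_coords(structure, chain = chain,
                                  representative = representative)
  nodes <- dplyr::inner_join(
    surf, coords,
    by = c("chain", "resno", "insert", "resid"))
  build_neighborhood_graph(nodes, cutoff = cutoff, convention = convention)
}
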