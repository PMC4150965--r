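#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' Computes per-atom solvent-accessible surface area (SASA) by rolling a probe
#' sphere over the heavy atoms: each atom is covered with an approximately
#' uniform point lattice on its expanded sphere (radius + probe) and the
#' accessible fraction is the fraction of points not buried inside any
#' neighbouring expanded sphere.
#'
#' @param xyz Numeric matrix (n x 3) of heavy-atom coordinates in Angstrom.
#' @param radii Numeric vector of van der Waals radii (Angstrom), length n.
#' @param probe Probe radius in Angstrom; 1.4 approximates a water molecule.
#' @param n_points Number of lattice points per atom sphere. More points give
#'   a finer area estimate; 960 keeps the quadrature error well under 1%.
#' @return Numeric vector of per-atom SASA values in Angstrom^2.
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(radii), all(radii > 0))
  n <- nrow(xyz)
  sphere <- .golden_spiral_points(n_points)
  rr <- radii + probe
  out <- numeric(n)
  # neighbour prune: atoms farther than r_i + r_j can never occlude each other
  max_rr <- max(rr)
  for (i in seq_len(n)) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (rr[i] + max_rr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rr[i] + rr[nb])^2]
    pts <- sphere * rr[i]
    pts <- sweep(pts, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      keep <- which(accessible)
      dj2 <- (pts[keep, 1] - xyz[j, 1])^2 + (pts[keep, 2] - xyz[j, 2])^2 +
        (pts[keep, 3] - xyz[j, 3])^2
      accessible[keep[dj2 < rr[j]^2]] <- FALSE
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(accessible) / n_points
  }
  out
}

# near-uniform points on the unit sphere (Fibonacci / golden-spiral lattice)
.golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue absolute and relative solvent accessibility
#'
#' Computes, for every standard amino-acid residue of a parsed structure, the
#' absolute solvent-accessible surface area `asa` (heavy atoms only) and the
#' relative accessibility `rasa = asa / asa_max(type)`, where `asa_max` is the
#' bundled per-type maximal area (see [max_asa_table()]). Residues of unknown
#' type are reported with a warning and excluded. RASA may slightly exceed 1
#' for unusually exposed residues (e.g. chain termini).
#'
#' @param structure A `bio3d` `pdb` object (from [bio3d::read.pdb()]) or a path
#'   to a PDB file.
#' @param chain Optional chain identifier(s) to restrict to.
#' @param probe,n_points Passed to [shrake_rupley()].
#' @return A tibble with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `asa`, `rasa`.
#' @export
compute_rasa <- function(structure, chain = NULL, probe = 1.4, n_points = 960L) {
  atoms <- .clean_atoms(structure, chain = chain)
  if (nrow(atoms) == 0) stop("no protein atoms found (empty chain?)")
  unknown <- setdiff(unique(atoms$resid), .standard_aa())
  if (length(unknown)) {
    warning("excluding residues of unknown amino-acid type: ",
            paste(unknown, collapse = ", "))
    atoms <- atoms[!(atoms$resid %in% unknown), , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("no standard amino-acid residues left")
  sasa <- shrake_rupley(as.matrix(atoms[, c("x", "y", "z")]),
                        .vdw_radius(atoms$elesy), probe = probe,
                        n_points = n_points)
  atoms$sasa <- sasa
  amax <- max_asa_table()
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid) |>
    dplyr::summarise(asa = sum(.data$sasa), .groups = "drop") |>
    dplyr::mutate(rasa = .data$asa / unname(amax[.data$resid])) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert) |>
    tibble::as_tibble()
}

# Parsed-structure hygiene shared by the surface-graph builders:
# protein ATOM records, heavy atoms, highest-occupancy altloc per atom,
# no waters/HETATM.
.clean_atoms <- function(structure, chain = NULL) {
  if (is.character(structure)) structure <- bio3d::read.pdb(structure)
  stopifnot(inherits(structure, "pdb"))
  at <- structure$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    substr(gsub("[^A-Za-z]", "", at$elty[is.na(at$elesy) | at$elesy == ""]), 1, 1)
  at <- at[toupper(at$elesy) != "H", , drop = FALSE]
  if (nrow(at) == 0) return(tibble::as_tibble(at))
  # keep the highest-occupancy alternate conformer of each atom
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$eleno), , drop = FALSE]
  tibble::as_tibble(at)
}
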