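#' Reference tables: maximal accessible surface areas and van der Waals radii
#'
#' `max_asa_table()` returns the theoretical maximally possible accessible
#' surface area per standard amino-acid type (Tien et al. 2013, "theoretical"
#' column), in square Angstrom. These are the denominators used to turn an
#' absolute solvent-accessible surface area into a relative one (RASA).
#'
#' `vdw_radius_table()` returns Bondi van der Waals radii per element, in
#' Angstrom, used both by the Shrake-Rupley surface computation and by the
#' van-der-Waals contact criteria for interface labeling.
#'
#' @return A named numeric vector (Angstrom^2 for `max_asa_table()`, Angstrom
#'   for `vdw_radius_table()`).
#' @export
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' @rdname max_asa_table
#' @export
vdw_radius_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

# radius lookup with a conservative default for exotic elements
.vdw_radius <- function(elements, default = 1.80) {
  tab <- vdw_radius_table()
  r <- unname(tab[toupper(elements)])
  r[is.na(r)] <- default
  r
}

.standard_aa <- function() names(max_asa_table())
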