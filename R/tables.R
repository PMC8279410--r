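#' Van der Waals radius sets
#'
#' Named atomic radius sets used to build the solvent-expanded spheres of the
#' Shrake-Rupley calculation. `"single"` is a Bondi-style per-element set for
#' heavy atoms (plus H, which is dropped by default upstream); `"protor"` is a
#' coarse group-style set with slightly larger carbon radii, as used by
#' area-per-group conventions.
#'
#' @param name radius set name, `"single"` or `"protor"`.
#' @return named numeric vector, element symbol -> radius in Angstrom.
#' @export
#' @examples
#' vdw_radii("single")[["C"]]
vdw_radii <- function(name = "single") {
  sets <- list(
    single = c(
      H = 1.20, C = 1.70, N = 1.55, O = 1.52,
      S = 1.80, P = 1.80, SE = 1.90, F = 1.47,
      CL = 1.75, BR = 1.85, I = 1.98
    ),
    protor = c(
      H = 1.00, C = 1.88, N = 1.64, O = 1.42,
      S = 1.77, P = 1.80, SE = 1.90, F = 1.47,
      CL = 1.75, BR = 1.85, I = 1.98
    )
  )
  if (!name %in% names(sets)) {
    stop("unknown radius set '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  }
  sets[[name]]
}

#' Theoretical maximum accessible surface area per residue type
#'
#' Theoretical maxima (Angstrom^2) for the 20 standard residues, used to
#' normalize residue ASA to relative solvent accessibility (RSA). These are
#' the theoretical values (upper bounds attainable by an unobstructed extended
#' conformation), not empirical Gly-X-Gly tripeptide averages.
#'
#' @return named numeric vector, 3-letter residue code -> max ASA in
#'   Angstrom^2.
#' @export
#' @examples
#' max_asa_table()[["ALA"]]
max_asa_table <- function() {
  c(
    ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
  )
}

# 1-letter <-> 3-letter residue code maps (standard amino acids).
.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
.aa1 <- stats::setNames(names(.aa3), unname(.aa3))
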