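# Amino-acid reference tables used by the descriptor module.

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of hydropathy values for the 20 standard amino acids
#' (one-letter codes). The grand average of these values over a residue
#' multiset is the GRAVY score.
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Theoretical maximum solvent-accessible surface areas
#'
#' Per-residue-type upper bounds on solvent-accessible surface area
#' (Tien et al. theoretical values, in square Angstrom), used to normalise
#' pocket SASA sums into a relative accessibility ratio.
#'
#' @format Named numeric vector of length 20.
#' @export
max_asa_theoretical <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Side-chain charge at pH 7: Asp/Glu -1, Lys/Arg +1, His +0.5, others 0.
aa_charge <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0,
  Q = 0, E = -1, G = 0, H = 0.5, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = 0, V = 0
)

aa_aromatic <- c("F", "W", "Y")

aa_three_letter <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

aa_one_letter <- stats::setNames(names(aa_three_letter), aa_three_letter)

# Van der Waals radii (Angstrom) by element, for sphere-point SASA.
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

check_residue_codes <- function(residue_types) {
  residue_types <- toupper(as.character(residue_types))
  bad <- setdiff(unique(residue_types), names(kyte_doolittle))
  if (length(bad) > 0L) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  residue_types
}
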