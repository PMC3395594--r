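# Amino-acid reference data shared across modules.

#' Standard amino-acid alphabet
#'
#' One-letter codes for the 20 standard amino acids, in the conventional
#' A,R,N,D,... order used throughout the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.AA1 <- structure(names(.AA3), names = unname(.AA3))

aa_three_letter <- function(aa1) {
  out <- .AA3[toupper(aa1)]
  if (anyNA(out)) stop("unknown amino-acid code: ",
                       paste(aa1[is.na(out)], collapse = ", "))
  unname(out)
}

aa_one_letter <- function(aa3) {
  out <- .AA1[toupper(aa3)]
  ifelse(is.na(out), "X", unname(out))
}

# Background amino-acid frequencies derived from the BLOSUM62 alignment set
# (Capra & Singh style background for divergence-based conservation scores).
.AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
  Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
  L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
  S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072)
.AA_BACKGROUND <- .AA_BACKGROUND / sum(.AA_BACKGROUND)

# Residue side-chain volumes (A^3), Zamyatnin (1972); used to rank
# similar-size substitutions.
.AA_VOLUME <- c(
  A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# Theoretical maximum accessible surface area (A^2) per residue in an
# extended Gly-X-Gly context (Tien et al. 2013, theoretical set); reference
# for relative solvent accessibility.
.AA_MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Van der Waals radii (A) for heavy elements in protein/ligand structures.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                MG = 1.73, ZN = 1.39, MN = 1.73, FE = 1.65, CA = 2.31,
                "NA" = 2.27, K = 2.75)

#' Physicochemical residue groups
#'
#' Charged and hydrophobic residue sets used in composition-enrichment
#' comparisons of catalytic versus allosteric pockets. Grouping is a
#' definition, not a result: the charged set is {D,E,K,R,H} and the
#' hydrophobic set {P,W,L,V,I,F,M,Y}; everything else is "other".
#'
#' @return Named list of character vectors `charged`, `hydrophobic`, `other`.
#' @export
aa_groups <- function() {
  charged <- c("D", "E", "K", "R", "H")
  hydrophobic <- c("P", "W", "L", "V", "I", "F", "M", "Y")
  list(charged = charged,
       hydrophobic = hydrophobic,
       other = setdiff(AA_ALPHABET1, c(charged, hydrophobic)))
}

# Wild type -> ordered neutral/hydrophobic similar-volume proposals.
# Anchored to substitutions realized experimentally in allosteric-site
# deregulation work (K->Q, R->I, Y->F/I, T->V, ...); user-configurable via
# TSV (see propose_substitutions).
.SUBSTITUTION_MAP <- list(
  K = c("Q", "I", "M"),
  R = c("I", "M", "Q"),
  E = c("Q", "L"),
  D = c("N", "L", "V"),
  H = c("F", "L"),
  Y = c("F", "I"),
  T = c("V"),
  S = c("A"),
  Q = c("I", "L"),
  N = c("L", "V"))
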