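# Amino acid lookup tables and side-chain propensity scales.

# Three-letter -> one-letter map for the 20 standard amino acids.
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Fixed alphabetical one-letter ordering used for composition vectors,
# PSSM columns, and every other 20-wide channel.
AA_ALPHABET <- sort(unname(AA_3TO1))

# Average residue masses (Da), monomer within a chain.
AA_MASS <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
  Q = 128.13, E = 129.12, G = 57.05, H = 137.14, I = 113.16,
  L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
  S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13
)

# Residue volumes (A^3), Zamyatnin.
AA_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

# Kyte-Doolittle hydropathy.
AA_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

minmax01 <- function(x) (x - min(x)) / (max(x) - min(x))

#' Side-chain propensity scales
#'
#' Six per-residue scales used as sequence-derived feature channels: mass,
#' volume, hydrophobicity (Kyte-Doolittle), C-beta branching (Ile/Thr/Val),
#' helix breaker (proline only) and side-chain electric charge. All scales are
#' min-max normalized to `[0, 1]`; charge uses the 3-level encoding
#' negative = 0, neutral = 0.5, positive = 1 (His counted neutral).
#'
#' @return Named list of six named numeric vectors, one value per standard
#'   amino acid (one-letter codes), all values in `[0, 1]`.
#' @export
propensity_scales <- function() {
  branch <- setNames(as.numeric(AA_ALPHABET %in% c("I", "T", "V")), AA_ALPHABET)
  helixb <- setNames(as.numeric(AA_ALPHABET == "P"), AA_ALPHABET)
  charge <- setNames(rep(0.5, 20), AA_ALPHABET)
  charge[c("D", "E")] <- 0
  charge[c("K", "R")] <- 1
  list(
    mass           = minmax01(AA_MASS[AA_ALPHABET]),
    volume         = minmax01(AA_VOLUME[AA_ALPHABET]),
    hydrophobicity = minmax01(AA_HYDROPATHY[AA_ALPHABET]),
    cbeta_branching = branch,
    helix_breaker  = helixb,
    charge         = charge
  )
}
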