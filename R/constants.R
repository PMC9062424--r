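# Monoisotopic mass bookkeeping. All masses in Da; residue masses are derived
# from elemental compositions so that isotope labels and neutral-formula
# modification deltas compose additively.

.ATOMIC_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.PROTON_MASS <- 1.0072764669
.MASS_C13_DELTA <- 13.0033548378 - 12
.MASS_N15_DELTA <- 15.0001088984 - 14.0030740052

# residue (= amino acid - H2O) elemental compositions, canonical 20 letters
.AA_FORMULA <- matrix(
  c( # C   H  N  O  S
    3,  5, 1, 1, 0, # A
    3,  5, 1, 1, 1, # C
    4,  5, 1, 3, 0, # D
    5,  7, 1, 3, 0, # E
    9,  9, 1, 1, 0, # F
    2,  3, 1, 1, 0, # G
    6,  7, 3, 1, 0, # H
    6, 11, 1, 1, 0, # I
    6, 12, 2, 1, 0, # K
    6, 11, 1, 1, 0, # L
    5,  9, 1, 1, 1, # M
    4,  6, 2, 2, 0, # N
    5,  7, 1, 1, 0, # P
    5,  8, 2, 2, 0, # Q
    6, 12, 4, 1, 0, # R
    3,  5, 1, 2, 0, # S
    4,  7, 1, 2, 0, # T
    5,  9, 1, 1, 0, # V
    11, 10, 2, 1, 0, # W
    9,  9, 1, 2, 0  # Y
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  c("C", "H", "N", "O", "S"))
)

.RESIDUE_MASS <- drop(.AA_FORMULA %*% .ATOMIC_MASS[colnames(.AA_FORMULA)])

.WATER_MASS <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
# C-terminal amide: NH2 replaces OH
.AMIDE_DELTA <- (.ATOMIC_MASS[["N"]] + 2 * .ATOMIC_MASS[["H"]]) -
  (.ATOMIC_MASS[["O"]] + .ATOMIC_MASS[["H"]])
# cyclopropane ring closure on Val: loss of two hydrogen atoms
.RING_DELTA <- -2 * .ATOMIC_MASS[["H"]]

.AA20 <- rownames(.AA_FORMULA)
.PROTEIN_ALPHABET <- c(.AA20, "X")
.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Monoisotopic mass constants
#'
#' Returns the atomic and derived constants used throughout the mass engine:
#' monoisotopic atomic masses, the proton mass, residue elemental formulas and
#' residue masses, the water and C-terminal amide deltas, the per-ring
#' cyclopropane delta (loss of two hydrogen atoms), and the isotope-label
#' deltas for \eqn{^{13}C} and \eqn{^{15}N}.
#'
#' @return A named list of constants (all masses in Da).
#' @examples
#' mass_constants()$residue_mass[["G"]] # 57.02146
#' @export
mass_constants <- function() {
  list(
    atomic_mass = .ATOMIC_MASS,
    proton_mass = .PROTON_MASS,
    water_mass = .WATER_MASS,
    amide_delta = .AMIDE_DELTA,
    ring_delta = .RING_DELTA,
    c13_delta = .MASS_C13_DELTA,
    n15_delta = .MASS_N15_DELTA,
    residue_formula = .AA_FORMULA,
    residue_mass = .RESIDUE_MASS
  )
}
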