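# Internal unit system: kcal/mol, Angstrom, femtosecond, Dalton (g/mol).

# Boltzmann constant, kcal/mol/K
.kB <- 0.0019872041

# m [Da] * v^2 [A^2/fs^2] -> kcal/mol:
# 1 g/mol * A^2/fs^2 = 1e-3 kg/mol * 1e-20 m^2 / 1e-30 s^2 = 1e7 J/mol
.mv2e <- 1e7 / 4184

# 1 kcal/mol/A^3 in GPa: 4184 J / 6.02214076e23 / 1e-30 m^3
.kcalA3_to_GPa <- 4184 / 6.02214076e23 * 1e30 / 1e9

#' Unit conversion constants
#'
#' Internal units are kcal/mol (energy), Angstrom (length), femtosecond
#' (time) and Dalton (mass). `mcf_constants()` returns the derived
#' conversion factors used throughout the package.
#'
#' @return Named list: `kB` (kcal/mol/K), `mv2e` (Da (A/fs)^2 to kcal/mol),
#'   `stress_GPa` (kcal/mol/A^3 to GPa).
#' @export
#' @examples
#' mcf_constants()$stress_GPa # ~6.9477
mcf_constants <- function() {
  list(kB = .kB, mv2e = .mv2e, stress_GPa = .kcalA3_to_GPa)
}
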