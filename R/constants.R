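#' Physical constants used throughout the package
#'
#' Lengths are Angstrom, energies kcal/mol, charges elementary charges,
#' times ns, temperatures K.
#'
#' @name constants
#' @keywords internal
NULL

# Boltzmann constant, kcal/mol/K
KB_KCAL <- 0.0019872

# Coulomb constant e^2/(4 pi eps0), kcal/mol * Angstrom / e^2
COULOMB_KCAL <- 332.0637

# Coulomb constant in V * Angstrom / e (potential of 1 e at 1 A, in volts)
COULOMB_VOLT <- 14.399645

# particles per nm^3 for a 1 M solution (Avogadro / 1e24)
PARTICLES_PER_NM3_PER_M <- 0.602214076

# closed vocabulary of atom group tags
ATOM_TAGS <- c(
  "wall_C", "carbonyl_C", "carbonyl_O", "graphene_C",
  "water_O", "water_H", "ion_K", "ion_Na", "ion_Cl"
)

CATION_TAGS <- c("ion_K", "ion_Na")

# element symbol for each group tag
TAG_ELEMENT <- c(
  wall_C = "C", carbonyl_C = "C", carbonyl_O = "O", graphene_C = "C",
  water_O = "O", water_H = "H", ion_K = "K", ion_Na = "Na", ion_Cl = "Cl"
)

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in K.
#' @return kT in kcal/mol.
#' @export
kT_kcal <- function(temperature = 300) KB_KCAL * temperature
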