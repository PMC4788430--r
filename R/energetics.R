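# Coarse-grained force field: harmonic bonds, WCA excluded volume,
# Debye-Hueckel screened Coulomb (cut at 4 Debye lengths, energy-shifted),
# optional single-coordinate harmonic restraints.  Every term is classified
# into the three-term decomposition E = E_tail + E_tail-rest + E_rest by the
# region labels of the beads it touches; the tail-scaffold tether bond is a
# cross term, so lowering lambda weakens but never severs the anchoring.

#' Force-field parameters
#'
#' @param bond_k harmonic bond constant (kcal/mol/Angstrom^2)
#' @param wca_epsilon WCA repulsion strength (kcal/mol)
#' @param dielectric relative dielectric constant (>= 1)
#' @param ionic_strength 1:1 electrolyte concentration (mol/L); the default
#'   0.153 M is the physiological salt condition
#' @param temperature temperature (K)
#' @param coulomb_constant Coulomb prefactor, kcal*Angstrom/(mol*e^2)
#' @param cutoff_debye_lengths nonbonded electrostatic cutoff, in units of
#'   the Debye length
#' @return an object of class `forcefield_params` carrying, in addition,
#'   the derived screening constant `kappa` (1/Angstrom) and `cutoff`
#'   (Angstrom)
#' @export
forcefield_params <- function(bond_k = 10,
                              wca_epsilon = 0.2,
                              dielectric = 80,
                              ionic_strength = 0.153,
                              temperature = 300,
                              coulomb_constant = COULOMB_CONSTANT,
                              cutoff_debye_lengths = 4) {
  for (nm in c("bond_k", "wca_epsilon", "dielectric", "ionic_strength",
               "temperature", "coulomb_constant", "cutoff_debye_lengths")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      abort_config(sprintf("%s must be a positive number", nm), nm)
  }
  if (dielectric < 1) abort_config("dielectric must be >= 1", "dielectric")
  ld <- debye_length(ionic_strength, temperature, dielectric,
                     coulomb_constant = coulomb_constant)
  structure(list(bond_k = as.numeric(bond_k),
                 wca_epsilon = as.numeric(wca_epsilon),
                 dielectric = as.numeric(dielectric),
                 ionic_strength = as.numeric(ionic_strength),
                 temperature = as.numeric(temperature),
                 coulomb_constant = as.numeric(coulomb_constant),
                 kappa = 1 / ld, debye = ld,
                 cutoff = as.numeric(cutoff_debye_lengths) * ld),
            class = "forcefield_params")
}

#' Debye screening length of a 1:1 electrolyte
#'
#' \eqn{\kappa^{-1} = (8 \pi \lambda_B N_A I)^{-1/2}} with the Bjerrum
#' length \eqn{\lambda_B = k_e / (\epsilon RT)}.  At 0.153 M, 300 K and
#' \eqn{\epsilon = 80} this is about 7.9 Angstrom.
#'
#' @param ionic_strength mol/L (1:1 electrolyte)
#' @param temperature K
#' @param dielectric relative dielectric constant
#' @param coulomb_constant kcal*Angstrom/(mol*e^2)
#' @return the screening length in Angstrom
#' @export
debye_length <- function(ionic_strength, temperature = 300, dielectric = 80,
                         coulomb_constant = COULOMB_CONSTANT) {
  if (any(c(ionic_strength, temperature, dielectric) <= 0))
    abort_config("ionic_strength, temperature and dielectric must be positive")
  bjerrum <- coulomb_constant / (dielectric * GAS_CONSTANT * temperature)
  n_per_A3 <- 6.02214076e23 * ionic_strength * 1e-27  # ions/A^3 per species
  1 / sqrt(8 * pi * bjerrum * n_per_A3)
}

#' Three-term energy decomposition of a configuration
#'
#' @param system a `cg_system`
#' @param positions N x 3 coordinates; defaults to the system's own
#' @param params a [forcefield_params()]
#' @return a list with class `energy_decomposition`: `e_tail`,
#'   `e_tail_rest`, `e_rest` (kcal/mol, unscaled by lambda)
#' @export
energy_decomposition <- function(system, positions = system$positions,
                                 params = forcefield_params()) {
  positions <- unname(as.matrix(positions))
  if (!all(is.finite(positions))) abort_numerical("non-finite coordinates")
  d <- energy_decomp_cpp(system, params, positions)
  structure(d, class = "energy_decomposition")
}

#' Total potential energy (sum of the three decomposition terms)
#' @param decomp an `energy_decomposition`
#' @return kcal/mol
#' @export
total_energy <- function(decomp) decomp$e_tail + decomp$e_tail_rest + decomp$e_rest

#' Forces under the lambda-scaled potential
#'
#' Negative gradient of \eqn{\lambda^2 E_{tail} + \lambda E_{tail-rest} +
#' E_{rest}} with respect to the mobile beads (immobile beads get zero).
#'
#' @param system a `cg_system`
#' @param positions N x 3 coordinates
#' @param lambda coupling value (> 0)
#' @param params a [forcefield_params()]
#' @return a list: `forces` (N x 3, kcal/mol/Angstrom) and the unscaled
#'   energy terms `e_tail`, `e_tail_rest`, `e_rest`
#' @export
cg_forces <- function(system, positions = system$positions, lambda = 1,
                      params = forcefield_params()) {
  if (lambda <= 0) abort_config("lambda must be > 0", "lambda")
  positions <- unname(as.matrix(positions))
  forces_cpp(system, params, positions, lambda)
}
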