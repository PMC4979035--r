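# Physical constants (CODATA 2018). Energies kcal/mol, lengths Angstrom,
# charges e, masses amu throughout the package.

#' Coulomb constant in kcal*Angstrom/(mol*e^2)
#'
#' Electrostatic conversion factor so that `k*q1*q2/r` with charges in
#' elementary charge units and distances in Angstrom yields kcal/mol.
#' @keywords internal
.kCoulomb <- 332.0636

.kBoltzmannJ  <- 1.380649e-23       # J/K
.hPlanckJ     <- 6.62607015e-34     # J*s
.cLightCm     <- 2.99792458e10      # cm/s
.avogadro     <- 6.02214076e23      # 1/mol
.amuKg        <- 1.66053906660e-27  # kg
.kcalJ        <- 4184               # J/kcal
.gasConstKcal <- 1.380649e-23 * 6.02214076e23 / 4184  # kcal/(mol*K)
.pressurePa   <- 101325             # 1 atm standard state

# sqrt(eigenvalue) -> wavenumber: eigenvalues of the mass-weighted Hessian
# carry kcal/mol/A^2/amu; conversion to cm^-1 is sqrt(lambda)*.freqFactor
.freqFactor <- sqrt(.kcalJ / .avogadro / 1e-20 / .amuKg) / (2 * pi * .cLightCm)
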