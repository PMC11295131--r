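# Physical constants (CODATA 2018, exact where the SI defines them).
# All internal computation is SI; Td, cm^2/(V s) and Angstrom^2 appear only at
# interfaces.

.kB    <- 1.380649e-23      # Boltzmann constant, J/K
.h     <- 6.62607015e-34    # Planck constant, J s
.e     <- 1.602176634e-19   # elementary charge, C
.u     <- 1.66053906660e-27 # unified atomic mass unit, kg
.Rgas  <- 8.314462618       # molar gas constant, J/(mol K)
.eps0  <- 8.8541878128e-12  # vacuum permittivity, F/m
.N0    <- 101325 / (.kB * 273.15)  # Loschmidt constant, m^-3 (= 2.6868e25)
.Td    <- 1e-21             # 1 Townsend in V m^2
.debye <- 3.33564e-30       # 1 Debye in C m
.fwhm  <- 2 * sqrt(2 * log(2))  # FWHM / sigma for a Gaussian

#' Physical constants used by driftIMS
#'
#' Returns the named physical constants the package computes with, all in SI
#' units.  Exposed mainly so that analysis scripts can stay numerically
#' consistent with the package (e.g. when converting reduced mobilities by
#' hand).
#'
#' @return Named numeric vector with elements `kB` (J/K), `h` (J s),
#'   `e` (C), `u` (kg), `Rgas` (J/(mol K)), `eps0` (F/m), `N0` (Loschmidt
#'   constant, m^-3), `Td` (V m^2) and `debye` (C m).
#' @examples
#' imsConstants()[["N0"]]   # 2.6868e25 m^-3
#' @export
imsConstants <- function() {
  c(kB = .kB, h = .h, e = .e, u = .u, Rgas = .Rgas,
    eps0 = .eps0, N0 = .N0, Td = .Td, debye = .debye)
}
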