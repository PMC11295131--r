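# Field-dependent ion transport: two-temperature theory (2TT) and the
# generalized Einstein relations (GER).

#' Construct gas conditions
#'
#' Closes the instrument conditions under the ideal-gas law: the number
#' density is N = p / (k_B T) and the field strength is E = (E/N) * N, with
#' the reduced field in Townsend (1 Td = 1e-21 V m^2).
#'
#' @param pressure gas pressure, Pa.
#' @param temperature background gas temperature, K.
#' @param reducedField reduced field strength E/N, Td.
#' @param gasMass molecular mass of the collision gas, u (default N2).
#' @return A [GasConditions] object.
#' @examples
#' g <- gasConditions(1470, 353.15, 120)   # 14.7 mbar, 80 C, 120 Td
#' numberDensity(g)   # 3.015e23 m^-3
#' fieldStrength(g)   # 3.618e4 V/m
#' @export
gasConditions <- function(pressure, temperature, reducedField,
                          gasMass = 28.013) {
  if (!is.finite(pressure) || pressure <= 0)
    stop("pressure must be positive (Pa)")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")
  if (!is.finite(reducedField) || reducedField < 0)
    stop("reducedField must be >= 0 (Td)")
  N <- pressure / (.kB * temperature)
  new("GasConditions", pressure = pressure, temperature = temperature,
      reducedField = reducedField, gasMass = gasMass,
      numberDensity = N, fieldStrength = reducedField * .Td * N)
}

#' Same gas at a different reduced field strength
#'
#' @param gas a [GasConditions] object.
#' @param reducedField new E/N, Td.
#' @return A [GasConditions] object with identical p, T, gas mass.
#' @export
withReducedField <- function(gas, reducedField) {
  gasConditions(gas@pressure, gas@temperature, reducedField, gas@gasMass)
}

#' Construct a per-species mobility model
#'
#' @param species species identifier.
#' @param ionMass ion mass, u.
#' @param k0Table reduced-mobility table: data.frame or matrix with columns
#'   `EN_td` (strictly increasing reduced field, Td) and `K0_cm2_Vs`
#'   (reduced mobility, cm^2/(V s)).  A single number is accepted as a
#'   field-independent mobility and expanded over 0-200 Td.
#' @param charge charge state, elementary charges (integer >= 1).
#' @param gasMass collision-gas mass, u.
#' @param corrections numeric(2) higher-order 2TT coefficients
#'   (alpha2TT for T_L, beta2TT for T_eff); default c(0, 0).
#' @param gammaL longitudinal field-energy partition coefficient
#'   (T_L = T + gammaL * M v_d^2 / k_B); default 2/3.
#' @return A [MobilityModel].
#' @examples
#' m <- mobilityModel("ion", 192.2, 1.519)      # constant mobility
#' reducedMass(m)                               # 24.45 u against N2
#' @export
mobilityModel <- function(species, ionMass, k0Table, charge = 1L,
                          gasMass = 28.013, corrections = c(0, 0),
                          gammaL = 2 / 3) {
  if (is.numeric(k0Table) && length(k0Table) == 1L)
    k0Table <- data.frame(EN_td = c(0, 200), K0_cm2_Vs = rep(k0Table, 2))
  tb <- as.matrix(as.data.frame(k0Table)[, c("EN_td", "K0_cm2_Vs")])
  storage.mode(tb) <- "double"
  new("MobilityModel", species = as.character(species), ionMass = ionMass,
      charge = as.integer(charge), gasMass = gasMass, k0Table = tb,
      corrections = as.numeric(corrections), gammaL = gammaL)
}

#' Ion-neutral reduced mass
#'
#' @param model a [MobilityModel].
#' @return Reduced mass m*M/(m+M), u.
#' @export
reducedMass <- function(model) {
  model@ionMass * model@gasMass / (model@ionMass + model@gasMass)
}

# Monotone cubic interpolant of the K0 table (Fritsch-Carlson).  Returns a
# function f(x, deriv) of E/N in Td giving K0 in cm^2/(V s) (deriv = 0) or its
# derivative per Td (deriv = 1).  Hard range error outside the table:
# extrapolating 2TT corrections silently is the dominant error source.
.k0fun <- function(model) {
  tb <- model@k0Table
  lo <- tb[1, 1]; hi <- tb[nrow(tb), 1]
  f <- stats::splinefun(tb[, 1], tb[, 2], method = "monoH.FC")
  function(x, deriv = 0) {
    if (any(x < lo - 1e-9) || any(x > hi + 1e-9))
      stop(sprintf(
        "E/N = %.6g Td outside mobility table range [%g, %g] Td for '%s' (extrapolation refused)",
        x[which(x < lo - 1e-9 | x > hi + 1e-9)[1]], lo, hi, model@species))
    f(pmin(pmax(x, lo), hi), deriv = deriv)
  }
}

#' Ion mobility at the applied field
#'
#' Interpolates the reduced-mobility table at the gas's E/N (monotone cubic)
#' and converts to the true mobility at the gas density,
#' K = K0(E/N) * (N0 / N), in SI units.
#'
#' @param model a [MobilityModel].
#' @param gas a [GasConditions]; its E/N must lie within the table range
#'   (extrapolation is refused).
#' @return Mobility K, m^2/(V s).
#' @examples
#' g <- gasConditions(1470, 353.15, 120)
#' mobilityAtField(mobilityModel("ion", 192.2, 1.519), g)  # 1.354e-2
#' @export
mobilityAtField <- function(model, gas) {
  k0 <- .k0fun(model)(gas@reducedField)
  k0 * 1e-4 * .N0 / gas@numberDensity
}

#' Fractional mobility change with field (alpha-function)
#'
#' alpha(E/N) = K0(E/N) / K0(lowest tabulated field) - 1; the dimensionless
#' deviation of the reduced mobility from its low-field value.  For typical
#' singly charged mid-sized ions it decreases by a few percent up to 120 Td.
#'
#' @param model a [MobilityModel].
#' @param reducedField E/N values, Td (within the table range).
#' @return Numeric vector of alpha values.
#' @export
alphaFunction <- function(model, reducedField) {
  f <- .k0fun(model)
  f(reducedField) / model@k0Table[1, 2] - 1
}

#' Drift velocity
#'
#' v_d = K * E at the applied reduced field.
#'
#' @inheritParams mobilityAtField
#' @return Drift velocity, m/s (>= 0).
#' @export
driftVelocity <- function(model, gas) {
  mobilityAtField(model, gas) * gas@fieldStrength
}

#' Effective ion temperature (two-temperature theory)
#'
#' T_eff = T + M v_d^2 / (3 k_B) * (1 + beta2TT), the temperature describing
#' the mean ion-neutral collision velocity distribution.  With the
#' higher-order coefficient beta2TT = 0 (default) this is first-order 2TT.
#' The ion's internal temperature is approximated by T_eff throughout the
#' kinetics (no explicit inelastic-collision treatment).
#'
#' @inheritParams mobilityAtField
#' @return T_eff, K.
#' @examples
#' g <- gasConditions(1470, 353.15, 120)
#' effectiveTemperature(mobilityModel("ion", 192.2, 1.519), g)  # 622.6 K
#' @export
effectiveTemperature <- function(model, gas) {
  v <- driftVelocity(model, gas)
  M <- gas@gasMass * .u
  gas@temperature + M * v^2 / (3 * .kB) * (1 + model@corrections[2])
}

#' Longitudinal ion temperature
#'
#' T_L = T + gammaL * M v_d^2 / k_B * (1 + alpha2TT): the temperature of the
#' collision-velocity distribution along the field axis, which receives more
#' than the isotropic 1/3 share of the field energy.  gammaL is configurable
#' per species (default 2/3); gammaL = 1/3 degenerates to T_eff.
#'
#' @inheritParams mobilityAtField
#' @return T_L, K (>= T_eff for gammaL >= 1/3).
#' @export
longitudinalTemperature <- function(model, gas) {
  v <- driftVelocity(model, gas)
  M <- gas@gasMass * .u
  gas@temperature +
    model@gammaL * M * v^2 / .kB * (1 + model@corrections[1])
}

#' Longitudinal diffusion coefficient (generalized Einstein relation)
#'
#' D_L = (k_B T_L / q) * d(K E)/dE, with the derivative taken analytically on
#' the monotone-cubic mobility interpolant:
#' d(K E)/dE = (N0/N) * (K0(x) + x K0'(x)) with x = E/N.  At zero field this
#' reduces to the Einstein relation D = k_B T K / q.
#'
#' @inheritParams mobilityAtField
#' @return D_L, m^2/s.
#' @examples
#' g0 <- gasConditions(1470, 353.15, 0)
#' longitudinalDiffusion(mobilityModel("ion", 192.2, 1.519), g0)  # 4.12e-4
#' @export
longitudinalDiffusion <- function(model, gas) {
  f <- .k0fun(model)
  x <- gas@reducedField
  dKEdE <- (f(x) + x * f(x, deriv = 1)) * 1e-4 * .N0 / gas@numberDensity
  TL <- longitudinalTemperature(model, gas)
  .kB * TL * dKEdE / (model@charge * .e)
}

#' All transport quantities at once
#'
#' @inheritParams mobilityAtField
#' @return Named numeric: `K` (m^2/(V s)), `vd` (m/s), `Teff` (K), `TL` (K),
#'   `DL` (m^2/s).
#' @export
transportState <- function(model, gas) {
  c(K = mobilityAtField(model, gas),
    vd = driftVelocity(model, gas),
    Teff = effectiveTemperature(model, gas),
    TL = longitudinalTemperature(model, gas),
    DL = longitudinalDiffusion(model, gas))
}

#' Collision cross section from reduced mobility (Mason-Schamp)
#'
#' Low-field Mason-Schamp relation
#' \deqn{\Omega = \frac{3 q}{16 N_0 K_0} \sqrt{\frac{2\pi}{\mu k_B T}}}
#' with \eqn{\mu} the ion-neutral reduced mass.  Valid in the low-field
#' limit only; at elevated E/N the field dependence of the mobility makes
#' the CCS derived this way field-dependent and hence ambiguous.
#'
#' @param k0 reduced mobility, cm^2/(V s).
#' @param ionMass ion mass, u.
#' @param gasMass collision-gas mass, u.
#' @param temperature gas temperature, K.
#' @param charge charge state, elementary charges.
#' @return Collision cross section, Angstrom^2.
#' @examples
#' ccsFromMobility(1.443, 192.2, 28.013, 353.15)  # 138.0 A^2
#' @export
ccsFromMobility <- function(k0, ionMass, gasMass, temperature, charge = 1L) {
  if (any(c(k0, ionMass, gasMass, temperature) <= 0) || charge < 1)
    stop("all arguments to ccsFromMobility must be positive")
  mu <- ionMass * gasMass / (ionMass + gasMass) * .u
  omega <- 3 * charge * .e / (16 * .N0 * k0 * 1e-4) *
    sqrt(2 * pi / (mu * .kB * temperature))
  omega * 1e20
}

#' Reduced mobility from a collision cross section
#'
#' Closed-form inverse of [ccsFromMobility()].
#'
#' @param ccs collision cross section, Angstrom^2.
#' @inheritParams ccsFromMobility
#' @return Reduced mobility K0, cm^2/(V s).
#' @export
mobilityFromCcs <- function(ccs, ionMass, gasMass, temperature, charge = 1L) {
  if (any(c(ccs, ionMass, gasMass, temperature) <= 0) || charge < 1)
    stop("all arguments to mobilityFromCcs must be positive")
  mu <- ionMass * gasMass / (ionMass + gasMass) * .u
  k0si <- 3 * charge * .e / (16 * .N0 * ccs * 1e-20) *
    sqrt(2 * pi / (mu * .kB * temperature))
  k0si * 1e4
}
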