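# Fixture scenarios: three instrument-realistic systems (a nonreacting
# mobility standard, a dynamically clustering protonated-methanol/water
# ensemble, a fragmenting protonated-ethyl-acetate ensemble) plus a seeded
# random-scenario generator with analytically solvable ground truth.
#
# Transport tables and cluster thermochemistry are *representative*: K0
# values near the published low-field mobilities with an alpha-function
# declining a few percent to 120 Td, binding free energies of order
# 40-100 kJ/mol chosen to place the population transitions at realistic
# reduced field strengths.  Printed rearrangement barriers of the ethyl
# acetate fragmentation network are used verbatim.

# quadratically declining reduced-mobility table (alpha-function -drop at
# 120 Td), tabulated out to `top` Td
.k0TableDecl <- function(k0low, drop = 0.03, top = 200) {
  x <- seq(0, top, by = 10)
  data.frame(EN_td = x, K0_cm2_Vs = k0low * (1 - drop * (x / 120)^2))
}

.ppmvToDensity <- function(ppmv, gas) ppmv * 1e-6 * gas@numberDensity

#' Nonreacting mobility standard: protonated 2,6-di-tert-butylpyridine
#'
#' One species (m/z 192), no reactions, low-field reduced mobility
#' 1.519 cm^2/(V s) in N2 declining 3 % to 120 Td.  Default conditions are
#' the stand-alone instrument's: 150.5 mm drift length, 14.7 mbar, 80 C,
#' 3 us injection.
#'
#' @return A [ScenarioBundle]; `reference$arrival(EN)` gives the closed-form
#'   drift time L / (K(E/N) E) and `reference$k0Low` the low-field mobility.
#' @export
dtbpSystem <- function() {
  gas <- gasConditions(1470, 353.15, 0)
  L <- 0.1505
  model <- mobilityModel("DtBP_H", 192.2, .k0TableDecl(1.519, 0.03, 200))
  net <- reactionNetwork(data.frame(name = "DtBP_H", mz = 192.2),
                         list(DtBP_H = model))
  ref <- list(
    tag = "closed_form", k0Low = 1.519, k0Expt = 1.443, ionMass = 192.2,
    arrival = function(EN) {
      g <- withReducedField(gas, EN)
      L / driftVelocity(model, g)
    })
  new("ScenarioBundle", name = "dtbp", network = net, gas = gas,
      driftLength = L, injectionTime = 3e-6, reference = ref)
}

#' Dynamically clustering system: protonated methanol + water
#'
#' Five ion species -- H+(MeOH)(H2O)n for n = 0, 1, 2 (m/z 33, 51, 69), the
#' proton-bound methanol dimer H+(MeOH)2 (m/z 65) and its monohydrate
#' (m/z 83) -- with reversible water association/dissociation (uniform
#' residual water) and methanol association from a neutral that decays
#' exponentially into the drift region.  Water chemistry is fast on the
#' drift-time scale (tens of events per ion); methanol chemistry is slow
#' (a few events), so the dimer appears as a separate, later peak while all
#' hydrates share one drift-time centroid.
#'
#' @param waterPpmv residual water volume mixing ratio, ppm_V (default 70).
#' @param meohProfile [NeutralProfile] for neutral methanol; default an
#'   exponential decay from 10 ppm_V at the injection end with e-folding
#'   length L/3.
#' @return A [ScenarioBundle] (MS-coupled conditions: 14.3 mbar, 27 C).
#' @export
meohWaterSystem <- function(waterPpmv = 70, meohProfile = NULL) {
  if (waterPpmv <= 0) stop("waterPpmv must be positive")
  gas <- gasConditions(1430, 300.15, 0)
  L <- 0.1505
  sp <- data.frame(
    name = c("bare", "mono", "di", "dimer", "dimerHyd"),
    mz = c(33.03, 51.05, 69.06, 65.06, 83.07))
  mass <- c(bare = 33.03, mono = 51.05, di = 69.06, dimer = 65.06,
            dimerHyd = 83.07)
  k0 <- c(bare = 2.70, mono = 2.45, di = 2.245, dimer = 2.00,
          dimerHyd = 1.85)
  mob <- lapply(sp$name, function(s)
    mobilityModel(s, mass[[s]], .k0TableDecl(k0[[s]], 0.02)))
  names(mob) <- sp$name
  water <- list(name = "H2O", mass = 18.015, polarizability = 1.45,
                dipole = 1.85,
                profile = neutralProfile("constant",
                                         .ppmvToDensity(waterPpmv, gas)))
  if (is.null(meohProfile))
    meohProfile <- neutralProfile("exponential_decay",
                                  .ppmvToDensity(10, gas), L / 3)
  meoh <- list(name = "MeOH", mass = 32.042, polarizability = 3.29,
               dipole = 1.70, profile = meohProfile)
  rx <- list(
    list(reactant = "bare", product = "mono", kind = "loose_association",
         dGassoc = -73, neutral = water),
    list(reactant = "mono", product = "di", kind = "loose_association",
         dGassoc = -44, neutral = water),
    list(reactant = "bare", product = "dimer", kind = "loose_association",
         dGassoc = -70, neutral = meoh),
    list(reactant = "dimer", product = "dimerHyd",
         kind = "loose_association", dGassoc = -40, neutral = water))
  net <- reactionNetwork(sp, mob, rx)
  new("ScenarioBundle", name = "meoh_water", network = net, gas = gas,
      driftLength = L, injectionTime = 3e-6,
      reference = list(tag = "closed_form", waterPpmv = waterPpmv))
}

#' Fragmenting system: protonated ethyl acetate
#'
#' Six species: the protonated parent (m/z 89), the two m/z 61 fragment
#' isomers (the doubly oxygen-protonated rearrangement product and the
#' weakly bound water adduct of the acylium ion, sharing one MS channel),
#' the acylium fragment (m/z 43), the parent monohydrate (m/z 107) and the
#' proton-bound dimer (m/z 177).  Rearrangement channels carry the published
#' free-energy barriers (133.5, 136.5 and 185.8 kJ/mol); water loss from the
#' weakly bound isomer and the clustering equilibria are barrierless capture
#' channels closed by detailed balance.  The 185.8 kJ/mol interconversion
#' makes the first fragment a stable intermediate, so the m/z 43 onset lies
#' at higher E/N than the m/z 61 onset.
#'
#' @param rateMultipliers optional named numeric, keys `"reactant->product"`,
#'   scaling individual channel rates (empirical fine-tuning hook; reverse
#'   rates of reversible channels are scaled identically, preserving
#'   detailed balance).
#' @return A [ScenarioBundle] (MS-coupled conditions).
#' @export
etoacSystem <- function(rateMultipliers = NULL) {
  gas <- gasConditions(1430, 300.15, 0)
  L <- 0.1505
  sp <- data.frame(
    name = c("EtOAcH", "frag61b", "frag61a", "frag43", "hydrate", "dimer"),
    mz = c(89.06, 61.03, 61.03, 43.02, 107.07, 177.11))
  mass <- c(EtOAcH = 89.06, frag61b = 61.03, frag61a = 61.03,
            frag43 = 43.02, hydrate = 107.07, dimer = 177.11)
  k0 <- c(EtOAcH = 2.00, frag61b = 2.25, frag61a = 2.25, frag43 = 2.55,
          hydrate = 1.85, dimer = 1.55)
  mob <- lapply(sp$name, function(s)
    mobilityModel(s, mass[[s]], .k0TableDecl(k0[[s]], 0.03)))
  names(mob) <- sp$name
  water <- list(name = "H2O", mass = 18.015, polarizability = 1.45,
                dipole = 1.85,
                profile = neutralProfile("constant", .ppmvToDensity(70, gas)))
  etoac <- list(name = "EtOAc", mass = 88.106, polarizability = 8.62,
                dipole = 1.78,
                profile = neutralProfile("exponential_decay",
                                         .ppmvToDensity(20, gas), L / 3))
  rx <- list(
    list(reactant = "EtOAcH", product = "frag61b", kind = "tight",
         barrier = 133.5),
    # McLafferty channel: comparable barrier but suppressed flux (the
    # weakly bound product makes this pathway non-dominant); the default
    # multiplier keeps the m/z 43 onset governed by the 185.8 kJ/mol step
    list(reactant = "EtOAcH", product = "frag61a", kind = "tight",
         barrier = 136.5, multiplier = 0.05),
    list(reactant = "frag61b", product = "frag61a", kind = "tight",
         barrier = 185.8),
    # water loss from the weakly bound isomer: fast relative to its
    # formation (the 185.8 kJ/mol step is rate-limiting), irreversible
    list(reactant = "frag61a", product = "frag43",
         kind = "loose_dissociation", dGassoc = -80, neutral = water),
    list(reactant = "EtOAcH", product = "hydrate",
         kind = "loose_association", dGassoc = -55, neutral = water),
    list(reactant = "EtOAcH", product = "dimer",
         kind = "loose_association", dGassoc = -65, neutral = etoac))
  if (!is.null(rateMultipliers)) {
    if (any(rateMultipliers <= 0)) stop("rate multipliers must be positive")
    for (i in seq_along(rx)) {
      key <- paste0(rx[[i]]$reactant, "->", rx[[i]]$product)
      if (key %in% names(rateMultipliers))
        rx[[i]]$multiplier <- unname(rateMultipliers[[key]])
    }
  }
  net <- reactionNetwork(sp, mob, rx)
  new("ScenarioBundle", name = "etoac", network = net, gas = gas,
      driftLength = L, injectionTime = 3e-6,
      reference = list(tag = "closed_form",
                       barriers = c(133.5, 136.5, 185.8)))
}

# classical RK4 integration of dP/dt = R P, independent of the
# matrix-exponential path; step sized so the stiffest rate is well resolved
.odeReference <- function(R, P0) {
  kmax <- max(-diag(R), 1)
  function(tEnd) {
    if (tEnd <= 0) return(P0)
    nstep <- max(2000L, ceiling(50 * kmax * tEnd))
    h <- tEnd / nstep
    P <- P0
    for (i in seq_len(nstep)) {
      k1 <- R %*% P
      k2 <- R %*% (P + h / 2 * k1)
      k3 <- R %*% (P + h / 2 * k2)
      k4 <- R %*% (P + h * k3)
      P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    as.numeric(P)
  }
}

#' Seeded random scenario with analytically solvable ground truth
#'
#' Generates a random network of 2-6 species with constant (field
#' independent) mobilities between 1 and 3 cm^2/(V s) and random
#' unimolecular interconversions whose rates are scaled relative to the
#' drift-time scale of the first species: `"fast"` gives every channel a
#' rate of at least 100 / t_D (the merged-peak regime), `"slow"` at most
#' 0.01 / t_D (resolved peaks), `"mixed"` draws each channel from either.
#' Rates are realised as tight-channel barriers solved from the Eyring
#' equation at the reactant's effective temperature under the bundle's
#' reference conditions (14.7 mbar, 80 C, 90 Td), so the generated network
#' exercises the same kinetics path as the physical fixtures.
#'
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param nSpecies number of species, 2-6 (default drawn from the seed).
#' @param regime `"fast"`, `"slow"` or `"mixed"`.
#' @return A [ScenarioBundle]; `reference$populations(t)` integrates the
#'   rate equations by brute force (RK4) independently of the
#'   matrix-exponential propagation path, `reference$equilibrium` is the
#'   stationary distribution and `reference$tD` the drift-time scale used
#'   for the rate scaling.
#' @export
randomScenario <- function(seed, nSpecies = NULL,
                           regime = c("fast", "slow", "mixed")) {
  regime <- match.arg(regime)
  set.seed(as.integer(seed))
  n <- if (is.null(nSpecies)) sample(2:6, 1) else as.integer(nSpecies)
  if (n < 2 || n > 6) stop("nSpecies must be in 2..6")
  gas <- gasConditions(1470, 353.15, 90)
  L <- 0.1505
  nm <- paste0("S", seq_len(n))
  mass <- round(stats::runif(n, 50, 250), 2)
  k0 <- round(stats::runif(n, 1, 3), 3)
  mob <- lapply(seq_len(n), function(i) mobilityModel(nm[i], mass[i], k0[i]))
  names(mob) <- nm
  tD <- L / driftVelocity(mob[[1]], gas)
  drawRate <- function() {
    fast <- switch(regime, fast = TRUE, slow = FALSE,
                   mixed = stats::runif(1) < 0.5)
    if (fast) stats::runif(1, 100, 500) / tD else
      stats::runif(1, 0.001, 0.01) / tD
  }
  rx <- list()
  for (i in seq_len(n - 1)) {
    # chain i -> i+1, randomly reversible
    for (pair in if (stats::runif(1) < 0.7)
           list(c(i, i + 1), c(i + 1, i)) else list(c(i, i + 1))) {
      k <- drawRate()
      Teff <- effectiveTemperature(mob[[pair[1]]], gas)
      barrier <- -.Rgas * Teff * log(k * .h / (.kB * Teff)) / 1e3
      rx[[length(rx) + 1L]] <-
        list(reactant = nm[pair[1]], product = nm[pair[2]], kind = "tight",
             barrier = max(barrier, 0))
    }
  }
  net <- reactionNetwork(data.frame(name = nm, mz = round(mass, 1)),
                         mob, rx)
  R <- buildRateMatrix(net, gas)
  P0 <- c(1, rep(0, n - 1))
  eig <- eigen(R)
  iz <- which.min(abs(eig$values))
  equil <- abs(Re(eig$vectors[, iz]))
  equil <- equil / sum(equil)
  new("ScenarioBundle", name = sprintf("random_%d_%s", seed, regime),
      network = net, gas = gas, driftLength = L, injectionTime = 3e-6,
      reference = list(tag = "ode", populations = .odeReference(R, P0),
                       equilibrium = stats::setNames(equil, nm), tD = tD,
                       regime = regime))
}

#' List the bundled fixture scenarios
#'
#' @return data.frame with `name` and `description`.
#' @export
listFixtures <- function() {
  data.frame(
    name = c("dtbp", "meoh_water", "etoac"),
    description = c(
      "nonreacting mobility standard (protonated 2,6-di-tert-butylpyridine)",
      "dynamic ion-water clustering of protonated methanol (5 species)",
      "fragmenting protonated ethyl acetate with clustering (6 species)"))
}

#' Fetch a fixture scenario by name
#' @param name one of the names in [listFixtures()].
#' @param ... passed to the fixture constructor.
#' @return A [ScenarioBundle].
#' @export
getFixture <- function(name, ...) {
  switch(name,
         dtbp = dtbpSystem(...),
         meoh_water = meohWaterSystem(...),
         etoac = etoacSystem(...),
         stop("unknown fixture: ", name))
}
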