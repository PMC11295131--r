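# Reaction kinetics: field/temperature dependent rate constants and the
# column-stochastic state-transition matrix that drives all chemistry.

#' Eyring rate constant for a tight transition state
#'
#' k = (k_B T_ion / h) exp(-dG / (R T_ion)) with transmission coefficient 1.
#' The ion's internal temperature is taken as its effective temperature at
#' the applied reduced field, so rearrangement/fragmentation rates grow
#' steeply with E/N.
#'
#' @param barrier free energy of activation, kJ/mol (>= 0).
#' @param Tion ion (internal) temperature, K.
#' @return First-order rate constant, 1/s.
#' @examples
#' eyringRate(133.5, 600)   # 29.9 /s
#' eyringRate(0, 600)       # k_B T / h = 1.25e13 /s
#' @export
eyringRate <- function(barrier, Tion) {
  if (any(Tion <= 0)) stop("Tion must be positive")
  if (any(barrier < 0)) stop("barrier must be >= 0 (kJ/mol)")
  (.kB * Tion / .h) * exp(-barrier * 1e3 / (.Rgas * Tion))
}

#' Capture rate coefficient for a barrierless (loose) association
#'
#' Langevin ion-induced-dipole capture,
#' k_L = q sqrt(pi alpha / (eps0 mu)) (temperature independent), multiplied
#' by an average-dipole-orientation style locking enhancement
#' 1 + c * mu_D / sqrt(4 pi eps0 alpha k_B T_eff) when the neutral carries a
#' permanent dipole.  The enhancement form is a documented fallback; the
#' locking constant (default 0.25) is exposed so an alternative capture model
#' can be matched.
#'
#' @param polarizability neutral polarizability volume, Angstrom^3.
#' @param dipole neutral permanent dipole moment, Debye.
#' @param reducedMass ion-neutral reduced mass, u.
#' @param Teff collision (effective) temperature, K; only used when
#'   `dipole > 0`.
#' @param lockingConstant dimensionless dipole-locking constant c.
#' @return Second-order capture rate coefficient, m^3/s.
#' @examples
#' captureRate(1.45, 0, 11.65)          # 8.26e-16 m^3/s (Langevin)
#' captureRate(1.45, 1.85, 11.65, 600)  # dipole-enhanced
#' @export
captureRate <- function(polarizability, dipole, reducedMass, Teff = NA_real_,
                        lockingConstant = 0.25) {
  if (polarizability <= 0) stop("polarizability must be positive (A^3)")
  if (reducedMass <= 0) stop("reducedMass must be positive (u)")
  alpha <- polarizability * 1e-30    # polarizability volume, m^3
  mu <- reducedMass * .u
  kL <- .e * sqrt(pi * alpha / (.eps0 * mu))
  if (dipole > 0) {
    if (!is.finite(Teff) || Teff <= 0)
      stop("Teff required (K) for a dipolar neutral")
    muD <- dipole * .debye
    kL <- kL * (1 + lockingConstant * muD /
                  sqrt(4 * pi * .eps0 * alpha * .kB * Teff))
  }
  kL
}

#' Dissociation rate by detailed balance against the capture rate
#'
#' Closes the reverse of a barrierless association thermodynamically: with
#' the pseudo-first-order equilibrium constant
#' K_eq = (c / c0) exp(-dG / (R T_eff)) (standard concentration c0 = the
#' Loschmidt constant N0), the dissociation rate is
#' k_r = k_f c / K_eq = k_f c0 exp(+dG / (R T_eff)),
#' independent of the actual neutral density.  An isolated
#' association/dissociation pair then equilibrates exactly to the Boltzmann
#' population ratio.
#'
#' @param forwardRate capture rate coefficient k_f of the association
#'   direction, m^3/s.
#' @param reactionFreeEnergy dG of the *association* direction, kJ/mol
#'   (negative for a bound cluster).
#' @param Teff effective temperature, K.
#' @param neutralDensity neutral number density, m^-3 (enters k_f c and K_eq
#'   identically and therefore cancels; accepted for interface symmetry).
#' @return First-order dissociation rate constant, 1/s.
#' @export
dissociationRate <- function(forwardRate, reactionFreeEnergy, Teff,
                             neutralDensity = .N0) {
  if (Teff <= 0) stop("Teff must be positive")
  if (neutralDensity < 0) stop("neutralDensity must be >= 0")
  forwardRate * .N0 * exp(reactionFreeEnergy * 1e3 / (.Rgas * Teff))
}

#' Construct a neutral concentration profile
#'
#' @param form `"constant"` or `"exponential_decay"`.
#' @param c0 number density at x = 0, m^-3.
#' @param lengthScale e-folding length, m (decay form only).
#' @return A [NeutralProfile].
#' @export
neutralProfile <- function(form = c("constant", "exponential_decay"),
                           c0, lengthScale = NA_real_) {
  form <- match.arg(form)
  new("NeutralProfile", form = form, c0 = c0,
      lengthScale = if (form == "constant") NA_real_ else lengthScale)
}

#' Evaluate a neutral concentration profile
#'
#' @param profile a [NeutralProfile].
#' @param position axial position(s) x >= 0, m.
#' @return Number density c(x), m^-3: `c0` for the constant form,
#'   `c0 * exp(-x / lengthScale)` for the decay form.
#' @export
neutralConcentration <- function(profile, position) {
  if (any(position < 0)) stop("position must be >= 0")
  switch(profile@form,
         constant = rep(profile@c0, length(position)),
         exponential_decay = profile@c0 * exp(-position / profile@lengthScale))
}

# -- network construction ---------------------------------------------------

.normalizeNeutral <- function(neutral) {
  if (is.null(neutral)) return(NULL)
  prof <- neutral$profile
  if (!is(prof, "NeutralProfile")) {
    prof <- neutralProfile(prof$form, prof$c0,
                           if (is.null(prof$lengthScale)) NA_real_
                           else prof$lengthScale)
  }
  list(name = neutral$name, mass = neutral$mass,
       polarizability = neutral$polarizability,
       dipole = if (is.null(neutral$dipole)) 0 else neutral$dipole,
       profile = prof)
}

.normalizeReaction <- function(rx) {
  kinds <- c("tight", "loose_association", "loose_dissociation")
  if (is.null(rx$kind) || !rx$kind %in% kinds)
    stop("reaction kind must be one of ", paste(kinds, collapse = ", "))
  out <- list(reactant = rx$reactant, product = rx$product, kind = rx$kind,
              barrier = rx$barrier %||% NA_real_,
              dGassoc = rx$dGassoc %||% NA_real_,
              neutral = .normalizeNeutral(rx$neutral),
              multiplier = rx$multiplier %||% 1,
              reversible = isTRUE(rx$reversible %||% (rx$kind == "loose_association")))
  if (out$kind == "tight") {
    if (!is.finite(out$barrier) || out$barrier < 0)
      stop(sprintf("tight reaction %s -> %s needs a barrier >= 0 (kJ/mol)",
                   out$reactant, out$product))
    out$reversible <- FALSE
  } else {
    if (is.null(out$neutral))
      stop(sprintf("loose reaction %s -> %s needs a neutral block",
                   out$reactant, out$product))
    if (!is.finite(out$dGassoc))
      stop(sprintf(
        "loose reaction %s -> %s needs dGassoc (association-direction dG, kJ/mol)",
        out$reactant, out$product))
  }
  if (out$multiplier <= 0) stop("rate multiplier must be positive")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a reaction network
#'
#' @param species data.frame with columns `name` and `mz` (Th), one row per
#'   ion species; distinct species (e.g. isomers) may share an m/z channel.
#' @param mobility named list of [MobilityModel] objects, names matching
#'   `species$name`.
#' @param reactions list of reaction descriptions, each a list with elements
#'   `reactant`, `product`, `kind` (`"tight"`, `"loose_association"`,
#'   `"loose_dissociation"`), and
#'   * for tight reactions: `barrier` (free energy of activation, kJ/mol);
#'   * for loose reactions: `dGassoc` (free energy of the *association*
#'     direction, kJ/mol; negative for a bound cluster) and a `neutral` block
#'     `list(name, mass (u), polarizability (A^3), dipole (D), profile)` with
#'     `profile` a [NeutralProfile] (or a list with `form`, `c0`,
#'     `lengthScale`).
#'   Associations are reversible by default: the paired dissociation (reverse
#'   rate closed by detailed balance) is generated automatically unless
#'   `reversible = FALSE`.  An optional `multiplier` scales the rate (the
#'   hook for empirical fine-tuning of individual channels).
#' @return A [ReactionNetwork].
#' @export
reactionNetwork <- function(species, mobility, reactions = list()) {
  species <- as.data.frame(species)
  rxs <- lapply(reactions, .normalizeReaction)
  # auto-generate the paired dissociation of reversible associations
  extra <- list()
  for (rx in rxs) {
    if (rx$kind == "loose_association" && rx$reversible) {
      extra[[length(extra) + 1L]] <-
        list(reactant = rx$product, product = rx$reactant,
             kind = "loose_dissociation", barrier = NA_real_,
             dGassoc = rx$dGassoc, neutral = rx$neutral,
             multiplier = rx$multiplier, reversible = FALSE, auto = TRUE)
    }
  }
  net <- new("ReactionNetwork", species = species,
             mobility = mobility[species$name], reactions = c(rxs, extra))
  validObject(net)
  net
}

#' Number of species in a network
#' @param network a [ReactionNetwork].
#' @return integer(1).
#' @export
nSpecies <- function(network) nrow(network@species)

#' Mobility model of one species
#' @param network a [ReactionNetwork].
#' @param species species name.
#' @return The species' [MobilityModel].
#' @export
mobilityOf <- function(network, species) {
  m <- network@mobility[[species]]
  if (is.null(m)) stop("unknown species: ", species)
  m
}

# -- rate matrix ------------------------------------------------------------

#' First-order rate matrix of a network at given conditions
#'
#' Off-diagonal entry R[i, j] >= 0 is the (pseudo-)first-order rate j -> i:
#' Eyring rates for tight channels, capture rate times the local neutral
#' concentration for associations, and detailed-balance closures for
#' dissociations.  All rates are evaluated at the *reactant* species'
#' effective temperature at the applied E/N.  Diagonals make every column
#' sum to zero (probability conservation).
#'
#' @param network a [ReactionNetwork].
#' @param gas a [GasConditions].
#' @param position axial position, m (enters only through nonconstant
#'   neutral profiles).
#' @return n x n rate matrix, 1/s, with species names on both dimensions.
#' @export
buildRateMatrix <- function(network, gas, position = 0) {
  sp <- network@species$name
  n <- length(sp)
  R <- matrix(0, n, n, dimnames = list(sp, sp))
  if (length(network@reactions) == 0) return(R)
  Teff <- vapply(sp, function(s)
    effectiveTemperature(network@mobility[[s]], gas), numeric(1))
  for (rx in network@reactions) {
    j <- match(rx$reactant, sp); i <- match(rx$product, sp)
    Tr <- Teff[j]
    k <- switch(rx$kind,
      tight = eyringRate(rx$barrier, Tr),
      loose_association = {
        nu <- rx$neutral
        mu <- network@mobility[[rx$reactant]]@ionMass * nu$mass /
          (network@mobility[[rx$reactant]]@ionMass + nu$mass)
        captureRate(nu$polarizability, nu$dipole, mu, Tr) *
          neutralConcentration(nu$profile, position)
      },
      loose_dissociation = {
        nu <- rx$neutral
        # capture direction: product ion + neutral -> reactant cluster
        mu <- network@mobility[[rx$product]]@ionMass * nu$mass /
          (network@mobility[[rx$product]]@ionMass + nu$mass)
        kf <- captureRate(nu$polarizability, nu$dipole, mu, Tr)
        dissociationRate(kf, rx$dGassoc, Tr,
                         neutralConcentration(nu$profile, position))
      })
    R[i, j] <- R[i, j] + k * rx$multiplier
  }
  diag(R) <- diag(R) - colSums(R)
  R
}

#' State-transition matrix over one time step
#'
#' phi(dt) = expm(R dt), the exact matrix exponential of the rate matrix:
#' entry (i, j) is the probability that a species-j ion has identity i after
#' dt.  Columns sum to one by construction.  A step-size guard refuses dt
#' for which any species' total reaction probability per step exceeds 5 %,
#' because the particle engine counts at most one reaction event per step.
#'
#' @param R n x n first-order rate matrix (columns summing to 0), 1/s.
#' @param dt time step, s.
#' @param context list recording the evaluation context (reduced field,
#'   position); informational.
#' @param guard maximum allowed off-diagonal column sum (default 0.05);
#'   set `check = FALSE` to skip (used internally where the exact
#'   exponential over a long interval is wanted, e.g. the transfer region).
#' @param check logical, enforce the guard.
#' @return A [TransitionMatrix].
#' @examples
#' R <- matrix(c(-1000, 1000, 0, 0), 2, 2)   # A -> B at 1000 /s
#' phiMatrix(transitionMatrix(R, 1e-6))[2, 1]  # 1 - exp(-1e-3)
#' @export
transitionMatrix <- function(R, dt, context = list(reducedField = NA_real_,
                                                   position = NA_real_),
                             guard = 0.05, check = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  phi <- as.matrix(Matrix::expm(Matrix::Matrix(R * dt)))
  phi[phi < 0] <- 0
  phi <- sweep(phi, 2, colSums(phi), "/")
  dimnames(phi) <- dimnames(R)
  if (check) {
    off <- colSums(phi) - diag(phi)
    if (any(off > guard))
      stop(sprintf(
        "step-size guard: per-step reaction probability %.3g > %.3g for species %s; reduce dt",
        max(off), guard,
        if (is.null(colnames(phi))) which.max(off) else
          colnames(phi)[which.max(off)]))
  }
  new("TransitionMatrix", phi = phi, dt = dt, context = context)
}

# Sample positions at which rate matrices must be evaluated: a single node
# for position-independent chemistry, else a uniform cell grid over [0, L].
.positionGrid <- function(network, driftLength, nCells = 256L) {
  varying <- any(vapply(network@reactions, function(rx)
    !is.null(rx$neutral) && rx$neutral$profile@form != "constant", logical(1)))
  if (!varying || length(network@reactions) == 0)
    return(list(mid = 0, edges = c(0, max(driftLength, 1)), n = 1L))
  edges <- seq(0, driftLength, length.out = nCells + 1L)
  list(mid = (edges[-1] + edges[-length(edges)]) / 2, edges = edges,
       n = as.integer(nCells))
}

# Largest total exit rate over species and grid positions; basis for the
# automatic time step.
.maxExitRate <- function(network, gas, grid) {
  mx <- 0
  for (x in grid$mid) {
    R <- buildRateMatrix(network, gas, x)
    mx <- max(mx, -min(diag(R)))
  }
  mx
}

#' Suggest a time step for propagation
#'
#' dt = min(0.045 / max total exit rate, minimal drift time / 500): the first
#' term keeps every species' per-step reaction probability under the 5 %
#' step-size guard (with 10 % headroom), the second resolves the arrival
#' time distribution of the fastest species.
#'
#' @param network a [ReactionNetwork].
#' @param gas a [GasConditions].
#' @param driftLength drift-tube length, m.
#' @return Time step, s.
#' @export
suggestTimestep <- function(network, gas, driftLength) {
  grid <- .positionGrid(network, driftLength)
  kmax <- .maxExitRate(network, gas, grid)
  vmax <- max(vapply(network@species$name, function(s)
    driftVelocity(network@mobility[[s]], gas), numeric(1)))
  if (vmax <= 0) stop("zero drift velocity: cannot size the time step")
  tDmin <- driftLength / vmax
  min(if (kmax > 0) 0.045 / kmax else Inf, tDmin / 500)
}
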