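#' @import methods
NULL

# ---------------------------------------------------------------------------
# GasConditions
# ---------------------------------------------------------------------------

#' Gas conditions inside the drift tube
#'
#' Holds pressure, background gas temperature, reduced field strength and the
#' derived quantities shared by all transport and kinetics computations: the
#' neutral number density N (ideal gas) and the electric field strength
#' E = (E/N) * N.
#'
#' @slot pressure numeric(1), Pa.
#' @slot temperature numeric(1), K.
#' @slot reducedField numeric(1), Td (1 Td = 1e-21 V m^2).
#' @slot gasMass numeric(1), mass of the collision gas in u.
#' @slot numberDensity numeric(1), m^-3, derived.
#' @slot fieldStrength numeric(1), V/m, derived.
#' @seealso [gasConditions()]
#' @export
setClass("GasConditions",
  representation(pressure = "numeric", temperature = "numeric",
                 reducedField = "numeric", gasMass = "numeric",
                 numberDensity = "numeric", fieldStrength = "numeric"))

setValidity("GasConditions", function(object) {
  msg <- character()
  if (length(object@pressure) != 1 || !is.finite(object@pressure) ||
      object@pressure <= 0)
    msg <- c(msg, "pressure must be a single positive number (Pa)")
  if (length(object@temperature) != 1 || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number (K)")
  if (length(object@reducedField) != 1 || !is.finite(object@reducedField) ||
      object@reducedField < 0)
    msg <- c(msg, "reducedField must be a single number >= 0 (Td)")
  if (object@gasMass <= 0)
    msg <- c(msg, "gasMass must be positive (u)")
  if (length(msg) == 0) {
    N <- object@pressure / (.kB * object@temperature)
    if (abs(object@numberDensity - N) > 1e-9 * N)
      msg <- c(msg, "numberDensity inconsistent with ideal-gas law")
    E <- object@reducedField * .Td * N
    if (abs(object@fieldStrength - E) > 1e-9 * max(E, 1e-300))
      msg <- c(msg, "fieldStrength inconsistent with reducedField * N")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MobilityModel
# ---------------------------------------------------------------------------

#' Per-species ion transport model
#'
#' A reduced-mobility table K0(E/N) together with the ion and gas masses and
#' charge state.  This is the sole source of drift velocity, effective and
#' longitudinal temperatures and the longitudinal diffusion coefficient for a
#' species; the table is typically produced by an external mobility calculator
#' or measured, and is interpolated monotone-cubically in E/N.
#'
#' @slot species character(1) species identifier.
#' @slot ionMass numeric(1), u.
#' @slot charge integer(1), elementary charges (>= 1).
#' @slot gasMass numeric(1), u.
#' @slot k0Table two-column matrix, `EN_td` (strictly increasing) and
#'   `K0_cm2_Vs` (> 0).
#' @slot corrections numeric(2): higher-order two-temperature-theory
#'   coefficients `alpha2TT` (enters T_L) and `beta2TT` (enters T_eff);
#'   both default 0 (first-order theory).
#' @slot gammaL numeric(1): partition coefficient of the field energy going
#'   into the longitudinal temperature, T_L = T + gammaL * M v_d^2 / k_B.
#'   Default 2/3; 1/3 recovers the isotropic T_eff.
#' @seealso [mobilityModel()], [transportState()]
#' @export
setClass("MobilityModel",
  representation(species = "character", ionMass = "numeric",
                 charge = "integer", gasMass = "numeric",
                 k0Table = "matrix", corrections = "numeric",
                 gammaL = "numeric"))

setValidity("MobilityModel", function(object) {
  msg <- character()
  tb <- object@k0Table
  if (!is.numeric(tb) || ncol(tb) != 2)
    msg <- c(msg, "k0Table must be a numeric two-column matrix (EN_td, K0_cm2_Vs)")
  else {
    if (nrow(tb) < 2)
      msg <- c(msg, "k0Table needs at least two rows")
    if (any(diff(tb[, 1]) <= 0))
      msg <- c(msg, "k0Table E/N values must be strictly increasing")
    if (any(tb[, 2] <= 0))
      msg <- c(msg, "k0Table mobilities must be positive")
  }
  if (object@ionMass <= 0) msg <- c(msg, "ionMass must be positive (u)")
  if (object@gasMass <= 0) msg <- c(msg, "gasMass must be positive (u)")
  if (object@charge < 1L) msg <- c(msg, "charge must be an integer >= 1")
  if (length(object@corrections) != 2)
    msg <- c(msg, "corrections must be numeric(2): (alpha2TT, beta2TT)")
  if (object@gammaL <= 0) msg <- c(msg, "gammaL must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# NeutralProfile
# ---------------------------------------------------------------------------

#' Neutral reaction-partner concentration profile along the drift axis
#'
#' Either spatially constant or exponentially decaying from the injection end
#' (x = 0), emulating a neutral that diffuses into the drift region from the
#' reaction region.
#'
#' @slot form character(1), `"constant"` or `"exponential_decay"`.
#' @slot c0 numeric(1), number density at x = 0, m^-3.
#' @slot lengthScale numeric(1), e-folding length in m (decay form only;
#'   ignored for constant profiles).
#' @seealso [neutralProfile()], [neutralConcentration()]
#' @export
setClass("NeutralProfile",
  representation(form = "character", c0 = "numeric", lengthScale = "numeric"))

setValidity("NeutralProfile", function(object) {
  msg <- character()
  if (!object@form %in% c("constant", "exponential_decay"))
    msg <- c(msg, "form must be 'constant' or 'exponential_decay'")
  if (object@c0 < 0) msg <- c(msg, "c0 must be >= 0 (m^-3)")
  if (object@form == "exponential_decay" &&
      (!is.finite(object@lengthScale) || object@lengthScale <= 0))
    msg <- c(msg, "exponential_decay requires a positive lengthScale (m)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ReactionNetwork
# ---------------------------------------------------------------------------

#' Reaction network of ion species
#'
#' Species (each with an m/z channel and its own [MobilityModel]) plus typed
#' reactions: `tight` (rearrangement over a free-energy barrier, Eyring rate
#' at the reactant's effective temperature), `loose_association` (barrierless
#' capture of a neutral, pseudo-first-order via the neutral concentration
#' profile) and `loose_dissociation` (reverse of a capture, closed via
#' detailed balance against the capture rate).
#'
#' Reactions are stored as validated lists; see [reactionNetwork()] for the
#' accepted fields.
#'
#' @slot species data.frame with columns `name`, `mz` (Th).
#' @slot mobility named list of [MobilityModel] objects, one per species.
#' @slot reactions list of validated reaction descriptions.
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", mobility = "list",
                 reactions = "list"))

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  sp <- object@species
  if (!all(c("name", "mz") %in% names(sp)))
    msg <- c(msg, "species data.frame needs columns 'name' and 'mz'")
  else {
    if (anyDuplicated(sp$name))
      msg <- c(msg, "species names must be unique")
    if (!setequal(names(object@mobility), sp$name))
      msg <- c(msg, "every species needs exactly one mobility model")
    else if (!all(vapply(object@mobility, is, TRUE, "MobilityModel")))
      msg <- c(msg, "mobility entries must be MobilityModel objects")
    for (rx in object@reactions) {
      if (!rx$reactant %in% sp$name || !rx$product %in% sp$name) {
        msg <- c(msg, sprintf("reaction %s -> %s references unknown species",
                              rx$reactant, rx$product))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TransitionMatrix
# ---------------------------------------------------------------------------

#' Column-stochastic reaction-probability matrix for one time step
#'
#' Entry (i, j) is the probability that a particle of species j has identity i
#' after a time step dt; columns sum to one.  Built as the exact matrix
#' exponential of the first-order rate matrix times dt.
#'
#' @slot phi numeric matrix, n x n, column-stochastic.
#' @slot dt numeric(1), s.
#' @slot context list carrying the reduced field (Td) and axial position (m)
#'   at which the rates were evaluated.
#' @seealso [transitionMatrix()]
#' @export
setClass("TransitionMatrix",
  representation(phi = "matrix", dt = "numeric", context = "list"))

setValidity("TransitionMatrix", function(object) {
  msg <- character()
  phi <- object@phi
  if (nrow(phi) != ncol(phi)) msg <- c(msg, "phi must be square")
  if (any(phi < -1e-12) || any(phi > 1 + 1e-12))
    msg <- c(msg, "phi entries must lie in [0, 1]")
  if (any(abs(colSums(phi) - 1) > 1e-12))
    msg <- c(msg, "phi columns must sum to 1 within 1e-12")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MCConfig / MCResult
# ---------------------------------------------------------------------------

#' Monte Carlo run configuration
#'
#' @slot nParticles integer(1), number of independent ion trajectories.
#' @slot dt numeric(1), time step in s; `NA` means choose automatically as
#'   min(step-size guard from the kinetics, minimal drift time / 500).
#' @slot seed integer(1), RNG seed for the run.
#' @slot transferTime numeric(1), s: extra field-free reaction time in the MS
#'   transfer region applied by [extendTransferRegion()].
#' @slot initialPulse list with `type` ("delta" or "rectangular") and `tInj`
#'   (s, shutter opening time for the rectangular pulse).
#' @slot maxSteps numeric(1), hard cap on time steps per run.
#' @slot tMax numeric(1), s; when finite the run records identities at fixed
#'   elapsed time instead of at the drift-length plane (used for
#'   fixed-time comparisons against the ensemble engine).
#' @seealso [mcConfig()], [simulateMC()]
#' @export
setClass("MCConfig",
  representation(nParticles = "integer", dt = "numeric", seed = "integer",
                 transferTime = "numeric", initialPulse = "list",
                 maxSteps = "numeric", tMax = "numeric"))

setValidity("MCConfig", function(object) {
  msg <- character()
  if (object@nParticles < 1L) msg <- c(msg, "nParticles must be >= 1")
  if (!is.na(object@dt) && object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (!object@initialPulse$type %in% c("delta", "rectangular"))
    msg <- c(msg, "initialPulse$type must be 'delta' or 'rectangular'")
  if (object@transferTime < 0) msg <- c(msg, "transferTime must be >= 0")
  if (object@maxSteps < 1) msg <- c(msg, "maxSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of a particle-based (Monte Carlo) drift-tube simulation
#'
#' @slot arrivals data.frame, one row per particle: `species` (identity at the
#'   detector plane), `arrival_s` (linearly interpolated crossing of x = L),
#'   and, after [extendTransferRegion()], `species_final` (identity after the
#'   transfer region).
#' @slot finalPopulations named numeric, arrival counts / nParticles, for the
#'   latest stage (transfer region if extended, else detector plane).
#' @slot eventCounts named numeric, mean number of reaction events per ion
#'   keyed `"reactant->product"`.
#' @slot config the [MCConfig] used.
#' @slot dt numeric(1), the time step actually used (s).
#' @slot gas the [GasConditions] of the run.
#' @slot driftLength numeric(1), m.
#' @slot extended logical(1), whether the transfer-region extension was run.
#' @export
setClass("MCResult",
  representation(arrivals = "data.frame", finalPopulations = "numeric",
                 eventCounts = "numeric", config = "MCConfig",
                 dt = "numeric", gas = "GasConditions",
                 driftLength = "numeric", extended = "logical"))

# ---------------------------------------------------------------------------
# EnsembleResult
# ---------------------------------------------------------------------------

#' Trajectory of the deterministic Markov-chain ensemble integrator
#'
#' @slot trajectory data.frame: `time_s`, `position_m`, then one relative
#'   population column per species.  Populations sum to 1 at every step.
#' @slot arrivalTime numeric(1), s: interpolated time at which the ensemble
#'   mean position crosses the drift length (NA when run to fixed time).
#' @slot finalPopulations named numeric at the last recorded step.
#' @export
setClass("EnsembleResult",
  representation(trajectory = "data.frame", arrivalTime = "numeric",
                 finalPopulations = "numeric"))

# ---------------------------------------------------------------------------
# ATD analysis containers
# ---------------------------------------------------------------------------

#' Arrival-time-distribution histogram
#'
#' @slot binEdges numeric, strictly increasing bin edges in s.
#' @slot counts matrix, one row per species, one column per bin.
#' @slot binWidth numeric(1), s (the instrument's ATD resolution).
#' @seealso [atdHistogram()], [fitGaussian()]
#' @export
setClass("ATDHistogram",
  representation(binEdges = "numeric", counts = "matrix",
                 binWidth = "numeric"))

setValidity("ATDHistogram", function(object) {
  msg <- character()
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (ncol(object@counts) != length(object@binEdges) - 1)
    msg <- c(msg, "counts must have one column per bin")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gaussian fit to an arrival-time peak
#'
#' @slot tD numeric(1), fitted peak centre (drift time), s.
#' @slot w05 numeric(1), fitted full width at half maximum, s
#'   (w05 = 2 sqrt(2 ln 2) sigma).
#' @slot amplitude numeric(1), fitted peak amplitude (counts).
#' @slot goodness numeric(1), RMS residual normalised by the amplitude.
#' @slot flagged logical(1), TRUE when the residual exceeds the non-Gaussian
#'   advisory threshold (5 % of the amplitude).
#' @export
setClass("GaussianFit",
  representation(tD = "numeric", w05 = "numeric", amplitude = "numeric",
                 goodness = "numeric", flagged = "logical"))

#' 2D IMS-MS spectrum
#'
#' Drift-time x m/z intensity histogram assembled from a Monte Carlo result;
#' the sum over m/z channels reproduces the total arrival-time distribution
#' bin for bin.
#'
#' @slot driftEdges numeric, drift-time bin edges, s.
#' @slot mz numeric, m/z channels (Th), one per row of `intensity`.
#' @slot intensity matrix of counts, length(mz) x (length(driftEdges) - 1).
#' @seealso [assemble2d()]
#' @export
setClass("Spectrum2D",
  representation(driftEdges = "numeric", mz = "numeric",
                 intensity = "matrix"))

setValidity("Spectrum2D", function(object) {
  msg <- character()
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (nrow(object@intensity) != length(object@mz))
    msg <- c(msg, "one intensity row per mz channel required")
  if (ncol(object@intensity) != length(object@driftEdges) - 1)
    msg <- c(msg, "one intensity column per drift bin required")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ScenarioBundle
# ---------------------------------------------------------------------------

#' A self-contained simulation scenario
#'
#' Bundles a reaction network with default gas conditions and, where
#' derivable, closed-form reference solutions used by the test suite.
#'
#' @slot name character(1).
#' @slot network a [ReactionNetwork].
#' @slot gas default [GasConditions] (pressure/temperature; the reduced field
#'   is varied per run with [withReducedField()]).
#' @slot driftLength numeric(1), m.
#' @slot injectionTime numeric(1), s.
#' @slot reference list of reference solutions, each tagged with its
#'   derivation (`"closed_form"` or `"ode"`).
#' @export
setClass("ScenarioBundle",
  representation(name = "character", network = "ReactionNetwork",
                 gas = "GasConditions", driftLength = "numeric",
                 injectionTime = "numeric", reference = "list"))
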