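# The two integrators: deterministic Markov-chain ensemble propagation and
# the per-particle Monte Carlo engine with reaction sampling and random-walk
# diffusion, plus the MS transfer-region extension and field scans.

#' Monte Carlo run configuration
#'
#' @param nParticles number of ion trajectories (default 4000).
#' @param dt time step, s; `NA` (default) picks
#'   min(kinetics step-size guard, minimal drift time / 500), see
#'   [suggestTimestep()].
#' @param seed RNG seed.
#' @param transferTime MS transfer-region reaction time, s (default 50 us).
#' @param initialPulse `"delta"` (zero initial width, default) or
#'   `"rectangular"` with shutter opening time `tInj`.
#' @param tInj shutter opening time for the rectangular pulse, s.
#' @param maxSteps hard cap on propagation steps (runaway protection).
#' @param tMax finite value switches to fixed-time mode: identities are
#'   recorded when each particle's clock reaches `tMax` rather than at the
#'   drift-length plane.
#' @return An [MCConfig].
#' @export
mcConfig <- function(nParticles = 4000L, dt = NA_real_, seed = 1L,
                     transferTime = 50e-6,
                     initialPulse = c("delta", "rectangular"),
                     tInj = 3e-6, maxSteps = 1e7, tMax = Inf) {
  initialPulse <- match.arg(initialPulse)
  new("MCConfig", nParticles = as.integer(nParticles), dt = dt,
      seed = as.integer(seed), transferTime = transferTime,
      initialPulse = list(type = initialPulse, tInj = tInj),
      maxSteps = maxSteps, tMax = tMax)
}

# Per-cell transition matrices as a cumulative n x n x ncell array for the
# compiled core, plus the plain matrices.
.phiCache <- function(network, gas, dt, grid, guard = 0.05, check = TRUE) {
  n <- nSpecies(network)
  cum <- array(0, dim = c(n, n, grid$n))
  phis <- vector("list", grid$n)
  for (c in seq_len(grid$n)) {
    tm <- transitionMatrix(buildRateMatrix(network, gas, grid$mid[c]), dt,
                           context = list(reducedField = gas@reducedField,
                                          position = grid$mid[c]),
                           guard = guard, check = check)
    phis[[c]] <- tm@phi
    cum[, , c] <- apply(tm@phi, 2, cumsum)
  }
  list(cum = cum, phis = phis)
}

.speciesTransport <- function(network, gas) {
  sp <- network@species$name
  v <- vapply(sp, function(s) driftVelocity(network@mobility[[s]], gas),
              numeric(1))
  D <- vapply(sp, function(s)
    longitudinalDiffusion(network@mobility[[s]], gas), numeric(1))
  list(v = v, D = D)
}

#' One Monte Carlo particle step (reference implementation)
#'
#' Resamples the particle identity from the transition matrix's column for
#' its current species, then advances the position by the *new* identity's
#' drift step K E dt plus a diffusion step of magnitude sqrt(2 D_L dt) whose
#' sign is a fair coin, and advances the clock by dt.  This is the
#' plain-R reference for the compiled lockstep engine inside [simulateMC()];
#' it consumes two uniform deviates from R's RNG per call.
#'
#' @param particle list with `species` (name), `position` (m), `clock` (s)
#'   and `events` (named counter, may be empty).
#' @param phi a [TransitionMatrix] whose dimnames index the species.
#' @param v named per-species drift velocities, m/s.
#' @param DL named per-species longitudinal diffusion coefficients, m^2/s.
#' @param dt time step, s (must equal the step phi was built for).
#' @return The advanced particle (same structure).
#' @export
mcStep <- function(particle, phi, v, DL, dt) {
  p <- phi@phi
  j <- match(particle$species, colnames(p))
  if (is.na(j)) stop("particle identity not indexed in phi")
  u <- stats::runif(1)
  i <- which(u <= cumsum(p[, j]))[1]
  if (i != j) {
    key <- paste0(colnames(p)[j], "->", colnames(p)[i])
    particle$events[key] <- (particle$events[key] %||% 0) + 1
  }
  particle$species <- colnames(p)[i]
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  particle$position <- particle$position + v[[particle$species]] * dt +
    sgn * sqrt(2 * DL[[particle$species]] * dt)
  particle$clock <- particle$clock + dt
  particle
}

#' Particle-based (Monte Carlo) drift-tube simulation
#'
#' Propagates `nParticles` independent ions through the drift tube.  Each
#' time step samples possible reactions from the state-transition matrix and
#' moves the particle by drift plus a random-walk diffusion step, both
#' evaluated for the current identity at the applied E/N.  A particle
#' terminates when it crosses the drift length; the crossing time is linearly
#' interpolated within the final step and its identity at that moment is
#' recorded.  Results are bit-reproducible for a fixed seed.
#'
#' @param network a [ReactionNetwork].
#' @param gas a [GasConditions].
#' @param driftLength drift-tube length, m.
#' @param config an [MCConfig].
#' @param initialPopulations named numeric over species (summing to 1) from
#'   which initial identities are drawn; default: all particles start as the
#'   first species.
#' @return An [MCResult].
#' @examples
#' b <- dtbpSystem()
#' res <- simulateMC(b@network, withReducedField(b@gas, 120), b@driftLength,
#'                   mcConfig(nParticles = 200, seed = 7))
#' mean(arrivals(res)$arrival_s)   # ~ 307 us
#' @export
simulateMC <- function(network, gas, driftLength, config = mcConfig(),
                       initialPopulations = NULL) {
  validObject(config)
  sp <- network@species$name
  n <- length(sp)
  dt <- config@dt
  if (is.na(dt)) dt <- suggestTimestep(network, gas, driftLength)
  grid <- .positionGrid(network, driftLength)
  cache <- .phiCache(network, gas, dt, grid)
  tr <- .speciesTransport(network, gas)
  np <- config@nParticles

  set.seed(config@seed)
  if (is.null(initialPopulations)) {
    ids0 <- rep(1L, np)
  } else {
    P0 <- initialPopulations[sp]
    if (any(is.na(P0)) || abs(sum(P0) - 1) > 1e-8)
      stop("initialPopulations must be named over all species and sum to 1")
    ids0 <- sample.int(n, np, replace = TRUE, prob = P0)
  }
  t0 <- if (config@initialPulse$type == "rectangular")
    stats::runif(np, 0, config@initialPulse$tInj) else rep(0, np)

  out <- mc_core(ids0, rep(0, np), t0, unname(tr$v),
                 unname(sqrt(2 * tr$D * dt)), as.numeric(cache$cum),
                 grid$n, driftLength, dt, config@tMax, config@maxSteps)

  counts <- tabulate(out$id, nbins = n)
  pops <- stats::setNames(counts / np, sp)
  ev <- out$events / np
  keys <- outer(sp, sp, function(a, b) paste0(b, "->", a))
  nz <- which(ev > 0)
  evNamed <- stats::setNames(as.numeric(ev[nz]), keys[nz])

  new("MCResult",
      arrivals = data.frame(species = sp[out$id],
                            arrival_s = as.numeric(out$arrival)),
      finalPopulations = pops, eventCounts = evNamed, config = config,
      dt = dt, gas = gas, driftLength = driftLength, extended = FALSE)
}

#' Extend a Monte Carlo result through the MS transfer region
#'
#' After arriving at the detector plane, ions spend additional time (default
#' 50 us, the delay between the second ion gate and the ToF pusher) in the
#' transfer region before mass analysis.  Transfer is assumed soft: ion
#' temperatures stay at their drift-region values and there is no spatial
#' motion, so each arrived particle's identity simply evolves under the exact
#' transition matrix expm(R * transferTime) evaluated at the end of the
#' tube.  Arrival times are unchanged; for slow (kinetically shifted)
#' chemistry the populations can change substantially, placing fragment
#' intensity at the precursor's drift time.
#'
#' @param result an [MCResult] from [simulateMC()].
#' @param network the [ReactionNetwork] that produced it.
#' @param transferTime reaction time in the transfer region, s; defaults to
#'   the value in the result's config.
#' @return The [MCResult] with a `species_final` column in `arrivals` and
#'   updated `finalPopulations`; reaction-event counts still refer to the
#'   drift region only.
#' @export
extendTransferRegion <- function(result, network,
                                 transferTime = result@config@transferTime) {
  if (transferTime < 0) stop("transferTime must be >= 0")
  sp <- network@species$name
  arr <- result@arrivals
  if (transferTime == 0) {
    arr$species_final <- arr$species
  } else {
    R <- buildRateMatrix(network, result@gas, result@driftLength)
    phi <- transitionMatrix(R, transferTime, check = FALSE)@phi
    set.seed(result@config@seed + 1L)
    idx <- match(arr$species, sp)
    newIdx <- idx
    for (j in unique(idx)) {
      sel <- which(idx == j)
      newIdx[sel] <- sample.int(length(sp), length(sel), replace = TRUE,
                                prob = phi[, j])
    }
    arr$species_final <- sp[newIdx]
  }
  pops <- stats::setNames(
    tabulate(match(arr$species_final, sp), nbins = length(sp)) / nrow(arr), sp)
  methods::initialize(result, arrivals = arr, finalPopulations = pops,
                      extended = TRUE)
}

#' Deterministic Markov-chain ensemble propagation
#'
#' Propagates the relative species populations P by repeated application of
#' the state-transition matrix, P <- phi(dt) P, while the ensemble mean
#' position advances by the population-weighted ensemble drift velocity
#' <K>_ens E dt with <K>_ens = sum_i P_i K_i.  Terminates when the mean
#' position reaches the drift length (arrival time interpolated within the
#' final step) or, when `maxTime` is finite, at fixed elapsed time.
#'
#' @inheritParams simulateMC
#' @param dt time step, s; `NULL` picks [suggestTimestep()].
#' @param maxTime optional fixed propagation time, s.
#' @param stepCap stagnation protection: error after this many steps.
#' @return An [EnsembleResult] carrying the full recorded trajectory.
#' @examples
#' b <- dtbpSystem()
#' ens <- propagateEnsemble(b@network, withReducedField(b@gas, 120),
#'                          driftLength = b@driftLength)
#' arrivalTime(ens) * 1e6   # 307.3 us
#' @export
propagateEnsemble <- function(network, gas, dt = NULL, driftLength,
                              initialPopulations = NULL, maxTime = NULL,
                              stepCap = 5e6) {
  sp <- network@species$name
  n <- length(sp)
  if (is.null(dt)) dt <- suggestTimestep(network, gas, driftLength)
  grid <- .positionGrid(network, driftLength)
  cache <- .phiCache(network, gas, dt, grid)
  tr <- .speciesTransport(network, gas)
  P <- if (is.null(initialPopulations)) c(1, rep(0, n - 1)) else {
    P0 <- initialPopulations[sp]
    if (any(is.na(P0)) || abs(sum(P0) - 1) > 1e-8)
      stop("initialPopulations must be named over all species and sum to 1")
    as.numeric(P0)
  }
  fixedTime <- !is.null(maxTime) && is.finite(maxTime)
  nGuess <- if (fixedTime) ceiling(maxTime / dt) + 2L else
    min(stepCap, ceiling(driftLength / (max(tr$v) * dt)) * 4L) + 2L
  times <- positions <- numeric(nGuess)
  pops <- matrix(0, nGuess, n)
  x <- 0; t <- 0; step <- 1L
  times[1] <- 0; positions[1] <- 0; pops[1, ] <- P
  arrivalT <- NA_real_
  cellWidth <- if (grid$n > 1) driftLength / grid$n else Inf
  repeat {
    cell <- if (grid$n > 1)
      min(grid$n, max(1L, 1L + floor(x / cellWidth))) else 1L
    P <- as.numeric(cache$phis[[cell]] %*% P)
    vEns <- sum(P * tr$v)
    xOld <- x
    x <- x + vEns * dt
    t <- t + dt
    step <- step + 1L
    if (step > nGuess) {  # grow storage
      nGuess <- nGuess * 2L
      times <- c(times, numeric(length(times)))
      positions <- c(positions, numeric(length(positions)))
      pops <- rbind(pops, matrix(0, nrow(pops), n))
    }
    times[step] <- t; positions[step] <- x; pops[step, ] <- P
    if (!fixedTime && x >= driftLength) {
      arrivalT <- t - dt + dt * (driftLength - xOld) / (x - xOld)
      break
    }
    if (fixedTime && t >= maxTime) break
    if (step >= stepCap)
      stop("ensemble propagation stagnated (step cap reached); ",
           "is the ensemble mobility zero?")
  }
  traj <- data.frame(time_s = times[seq_len(step)],
                     position_m = positions[seq_len(step)])
  traj[sp] <- pops[seq_len(step), , drop = FALSE]
  new("EnsembleResult", trajectory = traj, arrivalTime = arrivalT,
      finalPopulations = stats::setNames(P, sp))
}

#' Species populations at the detector as a function of reduced field
#'
#' Runs one propagation per grid point at fixed drift length and returns the
#' species fractions at the detector plane, optionally also after the MS
#' transfer region.
#'
#' @param network a [ReactionNetwork].
#' @param gas base [GasConditions]; only its pressure/temperature are used,
#'   the reduced field is swept.
#' @param fields reduced-field grid, Td (each within all mobility tables).
#' @param engine `"ensemble"` (deterministic, default) or `"mc"`.
#' @param driftLength drift length, m.
#' @param config [MCConfig] for the MC engine; per grid point the seed is
#'   offset by the point index so fields are decorrelated but the whole scan
#'   stays reproducible.
#' @param transfer logical: also report populations after
#'   [extendTransferRegion()] (MC engine only).
#' @param initialPopulations see [simulateMC()].
#' @return data.frame with columns `EN_td`, `species`, `fraction`, `stage`
#'   (`"drift"` or `"transfer"`).
#' @export
fieldScan <- function(network, gas, fields, engine = c("ensemble", "mc"),
                      driftLength, config = mcConfig(), transfer = FALSE,
                      initialPopulations = NULL) {
  engine <- match.arg(engine)
  if (transfer && engine != "mc")
    stop("transfer-region populations require the mc engine")
  rows <- list()
  for (k in seq_along(fields)) {
    g <- withReducedField(gas, fields[k])
    if (engine == "ensemble") {
      ens <- propagateEnsemble(network, g, driftLength = driftLength,
                               initialPopulations = initialPopulations)
      pops <- finalPopulations(ens)
      rows[[length(rows) + 1L]] <-
        data.frame(EN_td = fields[k], species = names(pops),
                   fraction = as.numeric(pops), stage = "drift")
    } else {
      cfg <- methods::initialize(config, seed = config@seed + k - 1L)
      res <- simulateMC(network, g, driftLength, cfg, initialPopulations)
      pops <- finalPopulations(res)
      rows[[length(rows) + 1L]] <-
        data.frame(EN_td = fields[k], species = names(pops),
                   fraction = as.numeric(pops), stage = "drift")
      if (transfer) {
        ext <- extendTransferRegion(res, network)
        pops <- finalPopulations(ext)
        rows[[length(rows) + 1L]] <-
          data.frame(EN_td = fields[k], species = names(pops),
                     fraction = as.numeric(pops), stage = "transfer")
      }
    }
  }
  do.call(rbind, rows)
}
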