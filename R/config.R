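# Run configuration and the command front-end used by the CLI script.

.configDefaults <- function() {
  list(
    instrument = list(drift_length_mm = 150.5, pressure_mbar = 14.7,
                      temperature_C = 80, injection_time_us = 3,
                      atd_resolution_us = 0.056, gas_mass_u = 28.013),
    field = list(EN_td = 120),
    engine = list(type = "ensemble", n_particles = 4000L, dt_s = NULL,
                  seed = 1L, transfer_region = FALSE,
                  transfer_time_us = 50),
    network = list(fixture = "dtbp", path = NULL),
    output = list(dir = "driftims_out"))
}

.checkKeys <- function(block, allowed, name) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("config block '%s': unknown key(s) %s", name,
                 paste(sprintf("'%s'", unknown), collapse = ", ")))
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) with blocks `instrument`, `field`, `engine`, `network`,
#' `output`; all keys optional, defaults mirror the reference instrument
#' (150.5 mm drift length, 14.7 mbar, 80 C, 3 us injection, 56 ns ATD
#' resolution, 4000 particles).  Boundary units are instrument-friendly
#' (mm, mbar, degrees C, Td, us) and converted to SI once here.  Unknown
#' keys and unphysical values are rejected with the offending key named.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list merged over the file (e.g. from CLI flags),
#'   using `block.key` names such as `engine.seed`.
#' @return A validated config list (class `imsRunConfig`) with the raw
#'   blocks plus derived `$gas` ([GasConditions] family at the first grid
#'   field), `$fields`, `$driftLength`, `$injectionTime`.
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    .checkKeys(user, names(cfg), "top-level")
    for (blk in names(user)) {
      .checkKeys(user[[blk]], names(cfg[[blk]]), blk)
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    }
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(cfg) ||
        !parts[2] %in% names(cfg[[parts[1]]]))
      stop("unknown override key: ", key)
    cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
  }
  ins <- cfg$instrument
  if (ins$temperature_C <= -273.15)
    stop("instrument.temperature_C below absolute zero")
  if (ins$pressure_mbar <= 0) stop("instrument.pressure_mbar must be > 0")
  if (ins$drift_length_mm <= 0)
    stop("instrument.drift_length_mm must be > 0")
  fields <- unlist(cfg$field$EN_td)
  if (any(fields < 0)) stop("field.EN_td must be >= 0")
  if (!cfg$engine$type %in% c("ensemble", "mc"))
    stop("engine.type must be 'ensemble' or 'mc'")
  cfg$gas <- gasConditions(ins$pressure_mbar * 100,
                           ins$temperature_C + 273.15, fields[1],
                           ins$gas_mass_u)
  cfg$fields <- fields
  cfg$driftLength <- ins$drift_length_mm * 1e-3
  cfg$injectionTime <- ins$injection_time_us * 1e-6
  class(cfg) <- "imsRunConfig"
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML dump of the raw config blocks; embedded in
#' every output artifact so figures are regenerable from their sidecars.
#'
#' @param config an `imsRunConfig`.
#' @return character(1) hex digest.
#' @export
configHash <- function(config) {
  raw <- config[c("instrument", "field", "engine", "network", "output")]
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(raw, tf)
  unname(tools::md5sum(tf))
}

.resolveNetwork <- function(config) {
  if (!is.null(config$network$path)) return(readNetwork(config$network$path))
  getFixture(config$network$fixture)
}

.mcConfigFrom <- function(config) {
  eng <- config$engine
  mcConfig(nParticles = eng$n_particles,
           dt = if (is.null(eng$dt_s)) NA_real_ else eng$dt_s,
           seed = eng$seed, transferTime = eng$transfer_time_us * 1e-6,
           initialPulse = "rectangular", tInj = config$injectionTime)
}

#' Run a driftIMS command
#'
#' The programmatic equivalent of the shell entry point
#' (`inst/scripts/driftims`).  Subcommands: `simulate` (Monte Carlo run ->
#' per-particle CSV + JSON summary), `scan` (populations vs E/N table),
#' `fit` (Gaussian fit of the simulated ATD + reduced mobility, JSON),
#' `spectra2d` (drift-time x m/z CSV, long format) and `fixtures` (list the
#' bundled scenarios).  All artifacts embed the seed and config hash.
#'
#' @param subcommand one of `"simulate"`, `"scan"`, `"fit"`, `"spectra2d"`,
#'   `"fixtures"`.
#' @param config an `imsRunConfig` from [loadConfig()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a character vector of artifact paths written (empty
#'   for `fixtures`).
#' @export
runCommand <- function(subcommand = c("simulate", "scan", "fit",
                                      "spectra2d", "fixtures"),
                       config = loadConfig(), quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (subcommand == "fixtures") {
    fx <- listFixtures()
    if (!quiet) print(fx)
    return(invisible(character()))
  }
  dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  extra <- list(config_hash = hash,
                config = config[c("instrument", "field", "engine",
                                  "network")])
  bundle <- .resolveNetwork(config)
  network <- if (is(bundle, "ScenarioBundle")) bundle@network else bundle
  out <- function(f) file.path(config$output$dir, f)
  paths <- character()

  if (subcommand == "scan") {
    say("field scan over %d points (%s engine)", length(config$fields),
        config$engine$type)
    tab <- fieldScan(network, config$gas, config$fields,
                     engine = config$engine$type,
                     driftLength = config$driftLength,
                     config = .mcConfigFrom(config),
                     transfer = isTRUE(config$engine$transfer_region) &&
                       config$engine$type == "mc")
    p <- out("field_scan.csv")
    utils::write.csv(cbind(tab, config_hash = hash, seed = config$engine$seed),
                     p, row.names = FALSE)
    return(invisible(p))
  }

  # the remaining commands run one MC simulation at the first grid field
  cfg <- .mcConfigFrom(config)
  say("simulate: %d particles at %g Td (seed %d)", cfg@nParticles,
      config$gas@reducedField, cfg@seed)
  res <- simulateMC(network, config$gas, config$driftLength, cfg)
  if (isTRUE(config$engine$transfer_region))
    res <- extendTransferRegion(res, network)

  if (subcommand == "simulate") {
    paths <- writeMCResult(res, out("arrivals.csv"), out("summary.json"),
                           extra = extra)
  } else if (subcommand == "fit") {
    atd <- atdHistogram(res,
                        binWidth = config$instrument$atd_resolution_us * 1e-6)
    fit <- fitGaussian(atd)
    k0 <- reducedMobility(fit@tD, config$driftLength, config$gas)
    p <- out("fit.json")
    jsonlite::write_json(c(list(
      tD_s = fit@tD, w05_s = fit@w05, amplitude = fit@amplitude,
      goodness = fit@goodness, non_gaussian_flag = fit@flagged,
      K0_cm2_Vs = k0, seed = cfg@seed), extra), p,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- p
  } else if (subcommand == "spectra2d") {
    spec <- assemble2d(res, network,
                       binWidth = max(config$instrument$atd_resolution_us,
                                      1e-3) * 1e-6)
    centers <- (spec@driftEdges[-1] +
                  spec@driftEdges[-length(spec@driftEdges)]) / 2
    long <- data.frame(
      drift_time_s = rep(centers, each = length(spec@mz)),
      mz = rep(spec@mz, length(centers)),
      counts = as.numeric(spec@intensity))
    p <- out("spectrum2d.csv")
    utils::write.csv(cbind(long, config_hash = hash, seed = cfg@seed), p,
                     row.names = FALSE)
    paths <- p
  }
  say("wrote: %s", paste(paths, collapse = ", "))
  invisible(paths)
}
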