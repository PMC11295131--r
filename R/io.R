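# Serialization: mobility tables (CSV), reaction networks (YAML),
# Monte Carlo results (CSV + JSON summary).

#' Read / write a reduced-mobility table
#'
#' CSV with header columns `EN_td` (reduced field, Td, strictly increasing)
#' and `K0_cm2_Vs` (reduced mobility, cm^2/(V s)).
#'
#' @param path file path.
#' @return `readMobilityTable`: data.frame with the two columns.
#' @export
readMobilityTable <- function(path) {
  tb <- utils::read.csv(path)
  need <- c("EN_td", "K0_cm2_Vs")
  if (!all(need %in% names(tb)))
    stop("mobility table must have columns EN_td, K0_cm2_Vs: ", path)
  tb[need]
}

#' @rdname readMobilityTable
#' @param table data.frame with columns `EN_td`, `K0_cm2_Vs`.
#' @export
writeMobilityTable <- function(table, path) {
  utils::write.csv(table[c("EN_td", "K0_cm2_Vs")], path, row.names = FALSE)
  invisible(path)
}

.profileToList <- function(p) {
  out <- list(form = p@form, c0_m3 = p@c0)
  if (p@form == "exponential_decay") out$length_scale_m <- p@lengthScale
  out
}

.profileFromList <- function(x, where) {
  if (is.null(x$form) || is.null(x$c0_m3))
    stop("neutral profile needs 'form' and 'c0_m3' (", where, ")")
  neutralProfile(x$form, x$c0_m3,
                 if (is.null(x$length_scale_m)) NA_real_ else
                   x$length_scale_m)
}

#' Write a reaction network to a YAML config
#'
#' Serialises species (with inline mobility tables) and reactions in the
#' same structured format [readNetwork()] consumes.  Auto-generated reverse
#' channels of reversible associations are not written (they are regenerated
#' on read), so write -> read round-trips losslessly.
#'
#' @param network a [ReactionNetwork].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeNetwork <- function(network, path) {
  spl <- lapply(seq_len(nrow(network@species)), function(i) {
    s <- network@species$name[i]
    m <- network@mobility[[s]]
    list(name = s, mz = network@species$mz[i], mass_u = m@ionMass,
         charge = m@charge, gas_mass_u = m@gasMass, gamma_L = m@gammaL,
         alpha_2TT = m@corrections[1], beta_2TT = m@corrections[2],
         k0 = list(EN_td = as.numeric(m@k0Table[, 1]),
                   K0_cm2_Vs = as.numeric(m@k0Table[, 2])))
  })
  rxl <- list()
  for (rx in network@reactions) {
    if (isTRUE(rx$auto)) next
    out <- list(reactant = rx$reactant, product = rx$product,
                kind = rx$kind)
    if (rx$kind == "tight") out$barrier_kJmol <- rx$barrier
    else {
      out$dG_kJmol <- rx$dGassoc
      out$reversible <- rx$reversible
      nu <- rx$neutral
      out$neutral <- list(name = nu$name, mass_u = nu$mass,
                          polarizability_A3 = nu$polarizability,
                          dipole_D = nu$dipole,
                          profile = .profileToList(nu$profile))
    }
    if (rx$multiplier != 1) out$multiplier <- rx$multiplier
    rxl[[length(rxl) + 1L]] <- out
  }
  yaml::write_yaml(list(species = spl, reactions = rxl), path,
                   precision = 15)
  invisible(path)
}

#' Read a reaction network from a YAML config
#'
#' Expected structure: a `species` list (each with `name`, `mz`, `mass_u`,
#' optional `charge`, `gas_mass_u`, `gamma_L`, 2TT corrections, and a `k0`
#' block that is either inline `EN_td`/`K0_cm2_Vs` vectors, a `constant`
#' mobility, or a `file` pointing to a [readMobilityTable()] CSV relative to
#' the config), and a `reactions` list in the format documented in
#' [reactionNetwork()] with `barrier_kJmol` / `dG_kJmol` keys.  Validation
#' errors name the offending species or reaction.
#'
#' @param path YAML (or JSON) file path.
#' @return A [ReactionNetwork].
#' @export
readNetwork <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || length(cfg$species) == 0)
    stop("network config has no species: ", path)
  mob <- list()
  sp <- data.frame(name = character(), mz = numeric())
  for (i in seq_along(cfg$species)) {
    s <- cfg$species[[i]]
    where <- sprintf("species[%d]", i)
    for (key in c("name", "mz", "mass_u"))
      if (is.null(s[[key]]))
        stop(sprintf("%s: missing required key '%s'", where, key))
    k0 <- s$k0
    tb <- if (!is.null(k0$file)) {
      readMobilityTable(file.path(dirname(path), k0$file))
    } else if (!is.null(k0$constant)) {
      k0$constant
    } else if (!is.null(k0$EN_td)) {
      data.frame(EN_td = unlist(k0$EN_td),
                 K0_cm2_Vs = unlist(k0$K0_cm2_Vs))
    } else stop(where, ": k0 block needs 'file', 'constant' or inline ",
                "'EN_td'/'K0_cm2_Vs'")
    mob[[s$name]] <- mobilityModel(
      s$name, s$mass_u, tb, charge = s$charge %||% 1L,
      gasMass = s$gas_mass_u %||% 28.013,
      corrections = c(s$alpha_2TT %||% 0, s$beta_2TT %||% 0),
      gammaL = s$gamma_L %||% (2 / 3))
    sp <- rbind(sp, data.frame(name = s$name, mz = s$mz))
  }
  rxs <- lapply(seq_along(cfg$reactions), function(i) {
    r <- cfg$reactions[[i]]
    where <- sprintf("reactions[%d]", i)
    for (key in c("reactant", "product", "kind"))
      if (is.null(r[[key]]))
        stop(sprintf("%s: missing required key '%s'", where, key))
    nu <- NULL
    if (!is.null(r$neutral)) {
      n <- r$neutral
      nu <- list(name = n$name %||% "neutral", mass = n$mass_u,
                 polarizability = n$polarizability_A3,
                 dipole = n$dipole_D %||% 0,
                 profile = .profileFromList(n$profile, where))
      if (is.null(nu$mass) || is.null(nu$polarizability))
        stop(where, ": neutral block needs mass_u and polarizability_A3")
    }
    list(reactant = r$reactant, product = r$product, kind = r$kind,
         barrier = r$barrier_kJmol, dGassoc = r$dG_kJmol, neutral = nu,
         multiplier = r$multiplier %||% 1, reversible = r$reversible)
  })
  reactionNetwork(sp, mob, rxs)
}

#' Write a Monte Carlo result
#'
#' Writes a per-particle CSV (`species`, `arrival_s`, plus `species_final`
#' for transfer-extended results) and a JSON summary carrying the final
#' populations, mean reaction-event counts, seed, time step and a config
#' echo, so any figure is regenerable from its sidecar.
#'
#' @param result an [MCResult].
#' @param csvPath,jsonPath output paths; `NULL` skips that artifact.
#' @param extra named list merged into the JSON summary (e.g. a config
#'   hash).
#' @return Character vector of paths written, invisibly.
#' @export
writeMCResult <- function(result, csvPath, jsonPath = NULL, extra = list()) {
  written <- character()
  if (!is.null(csvPath)) {
    utils::write.csv(result@arrivals, csvPath, row.names = FALSE)
    written <- c(written, csvPath)
  }
  if (!is.null(jsonPath)) {
    cfg <- result@config
    summary <- c(list(
      populations = as.list(result@finalPopulations),
      event_counts = as.list(result@eventCounts),
      n_particles = cfg@nParticles, seed = cfg@seed, dt_s = result@dt,
      drift_length_m = result@driftLength,
      reduced_field_td = result@gas@reducedField,
      pressure_pa = result@gas@pressure,
      temperature_k = result@gas@temperature,
      transfer_extended = result@extended,
      package_version = as.character(utils::packageVersion("driftIMS"))),
      extra)
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, jsonPath)
  }
  invisible(written)
}
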