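# Generics and accessors.  Slots are never reached into from user code; these
# accessors are the supported surface.

#' @rdname speciesNames
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Species names of an object
#'
#' @param x a [ReactionNetwork], [ScenarioBundle] or [MCResult].
#' @return character vector of species identifiers, in network order.
#' @examples
#' speciesNames(dtbpSystem())
#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ScenarioBundle", function(x) x@network@species$name)

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "MCResult",
          function(x) names(x@finalPopulations))

#' @rdname accessors
#' @export
setGeneric("arrivals", function(x) standardGeneric("arrivals"))

#' Accessors for simulation results
#'
#' `arrivals()` returns the per-particle arrival table, `finalPopulations()`
#' the species fractions at the latest simulation stage, `eventCounts()` the
#' mean number of reaction events per ion keyed `"reactant->product"`, and
#' `trajectory()` the recorded time series of the ensemble integrator.
#'
#' @param x an [MCResult] or [EnsembleResult].
#' @return See details above.
#' @name accessors
#' @rdname accessors
#' @export
setMethod("arrivals", "MCResult", function(x) x@arrivals)

#' @rdname accessors
#' @export
setGeneric("finalPopulations", function(x) standardGeneric("finalPopulations"))

#' @rdname accessors
#' @export
setMethod("finalPopulations", "MCResult", function(x) x@finalPopulations)

#' @rdname accessors
#' @export
setMethod("finalPopulations", "EnsembleResult", function(x) x@finalPopulations)

#' @rdname accessors
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' @rdname accessors
#' @export
setMethod("eventCounts", "MCResult", function(x) x@eventCounts)

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname accessors
#' @export
setMethod("trajectory", "EnsembleResult", function(x) x@trajectory)

#' @rdname accessors
#' @export
setGeneric("arrivalTime", function(x) standardGeneric("arrivalTime"))

#' @rdname accessors
#' @export
setMethod("arrivalTime", "EnsembleResult", function(x) x@arrivalTime)

#' @rdname gas-accessors
#' @export
setGeneric("numberDensity", function(x) standardGeneric("numberDensity"))

#' Accessors for gas conditions
#'
#' @param x a [GasConditions] object.
#' @return numeric(1): the neutral number density (m^-3), electric field
#'   strength (V/m), reduced field (Td), pressure (Pa) or temperature (K).
#' @name gas-accessors
#' @rdname gas-accessors
#' @export
setMethod("numberDensity", "GasConditions", function(x) x@numberDensity)

#' @rdname gas-accessors
#' @export
setGeneric("fieldStrength", function(x) standardGeneric("fieldStrength"))

#' @rdname gas-accessors
#' @export
setMethod("fieldStrength", "GasConditions", function(x) x@fieldStrength)

#' @rdname gas-accessors
#' @export
setGeneric("reducedField", function(x) standardGeneric("reducedField"))

#' @rdname gas-accessors
#' @export
setMethod("reducedField", "GasConditions", function(x) x@reducedField)

#' @rdname gas-accessors
#' @export
setGeneric("gasPressure", function(x) standardGeneric("gasPressure"))

#' @rdname gas-accessors
#' @export
setMethod("gasPressure", "GasConditions", function(x) x@pressure)

#' @rdname gas-accessors
#' @export
setGeneric("gasTemperature", function(x) standardGeneric("gasTemperature"))

#' @rdname gas-accessors
#' @export
setMethod("gasTemperature", "GasConditions", function(x) x@temperature)

#' @rdname accessors
#' @export
setGeneric("phiMatrix", function(x) standardGeneric("phiMatrix"))

#' @rdname accessors
#' @export
setMethod("phiMatrix", "TransitionMatrix", function(x) x@phi)

# -- show methods -----------------------------------------------------------

setMethod("show", "GasConditions", function(object) {
  cat(sprintf(
    "GasConditions: %.4g mbar, %.2f K, %.4g Td (N = %.4g m^-3, E = %.4g V/m)\n",
    object@pressure / 100, object@temperature, object@reducedField,
    object@numberDensity, object@fieldStrength))
})

setMethod("show", "MobilityModel", function(object) {
  tb <- object@k0Table
  cat(sprintf(
    "MobilityModel '%s': m = %.4g u, z = %d, K0(%g Td) = %.4g cm^2/(V s), table %g-%g Td (%d points)\n",
    object@species, object@ionMass, object@charge, tb[1, 1], tb[1, 2],
    tb[1, 1], tb[nrow(tb), 1], nrow(tb)))
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions\n",
              nrow(object@species), length(object@reactions)))
  cat("  species:", paste(sprintf("%s (m/z %g)", object@species$name,
                                  object@species$mz), collapse = ", "), "\n")
  for (rx in object@reactions)
    cat(sprintf("  %s -> %s [%s]\n", rx$reactant, rx$product, rx$kind))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix (%d x %d), dt = %.3g s, E/N = %.3g Td\n",
              nrow(object@phi), ncol(object@phi), object@dt,
              object@context$reducedField))
})

setMethod("show", "MCResult", function(object) {
  cat(sprintf("MCResult: %d particles%s\n", nrow(object@arrivals),
              if (object@extended) " (transfer-region extended)" else ""))
  pops <- object@finalPopulations
  cat("  populations:", paste(sprintf("%s %.3f", names(pops), pops),
                              collapse = ", "), "\n")
  cat(sprintf("  mean arrival %.4g us, dt = %.3g s, seed = %d\n",
              mean(object@arrivals$arrival_s) * 1e6, object@dt,
              object@config@seed))
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d steps, arrival %.4g us\n",
              nrow(object@trajectory), object@arrivalTime * 1e6))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: tD = %.4g us, w05 = %.4g us, residual %.2g%%%s\n",
    object@tD * 1e6, object@w05 * 1e6, 100 * object@goodness,
    if (object@flagged) " [non-Gaussian?]" else ""))
})

setMethod("show", "Spectrum2D", function(object) {
  cat(sprintf("Spectrum2D: %d m/z channels x %d drift bins, %g counts\n",
              length(object@mz), ncol(object@intensity),
              sum(object@intensity)))
})

setMethod("show", "ScenarioBundle", function(object) {
  cat(sprintf("ScenarioBundle '%s': L = %.4g mm, %s\n", object@name,
              object@driftLength * 1e3,
              sprintf("%d species / %d reactions",
                      nrow(object@network@species),
                      length(object@network@reactions))))
})
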