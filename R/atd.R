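# Arrival-time-distribution analysis: histograms, Gaussian fits, reduced
# mobilities, analytic width budgets and their scaling limits, 2D spectra.

.binEdges <- function(times, binWidth) {
  lo <- floor(min(times) / binWidth) * binWidth
  hi <- ceiling(max(times) / binWidth + 1e-9) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  seq(lo, hi, by = binWidth)
}

#' Histogram a Monte Carlo result into an ATD
#'
#' @param result an [MCResult].
#' @param binWidth histogram bin width, s: the instrument's ATD resolution
#'   (56 ns for the stand-alone device, 3 us when MS-coupled).
#' @param useFinal use post-transfer identities (`species_final`) for the
#'   species split; default uses them when the result was extended.
#' @return An [ATDHistogram] with one row per species plus the bin edges.
#' @export
atdHistogram <- function(result, binWidth = 56e-9,
                         useFinal = result@extended) {
  arr <- result@arrivals
  sp <- names(result@finalPopulations)
  ids <- if (useFinal && !is.null(arr$species_final))
    arr$species_final else arr$species
  edges <- .binEdges(arr$arrival_s, binWidth)
  counts <- t(vapply(sp, function(s) {
    h <- graphics::hist(arr$arrival_s[ids == s], breaks = edges,
                        plot = FALSE)
    h$counts
  }, numeric(length(edges) - 1)))
  new("ATDHistogram", binEdges = edges, counts = counts,
      binWidth = binWidth)
}

#' Fit a Gaussian to an arrival-time peak
#'
#' Least-squares Gaussian on the bin centres, initialised from the histogram
#' moments, with the width bounded below by the bin width.  The fit is
#' advisory-flagged as non-Gaussian when the RMS residual exceeds 5 % of the
#' fitted amplitude (e.g. for bimodal or strongly tailed peaks); no silent
#' single-Gaussian answer is given in that regime -- inspect `flagged`.
#'
#' @param atd an [ATDHistogram].
#' @param species species name, or `"total"` (default) for the summed ATD.
#' @return A [GaussianFit]: centre `tD`, FWHM `w05` = 2 sqrt(2 ln 2) sigma,
#'   amplitude, normalised residual and the advisory flag.
#' @export
fitGaussian <- function(atd, species = "total") {
  y <- if (identical(species, "total")) colSums(atd@counts) else {
    if (!species %in% rownames(atd@counts))
      stop("unknown species: ", species)
    atd@counts[species, ]
  }
  x <- (atd@binEdges[-1] + atd@binEdges[-length(atd@binEdges)]) / 2
  nz <- sum(y > 0)
  if (nz < 2 || (nz == 1 && sum(y) > 0))
    stop("degenerate histogram: all mass in one bin, cannot fit a width")
  if (nz < 5)
    stop("need at least 5 nonzero bins for a Gaussian fit (got ", nz, ")")
  w <- y / sum(y)
  mu0 <- sum(w * x)
  s0 <- max(sqrt(sum(w * (x - mu0)^2)), atd@binWidth)
  a0 <- max(y)
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
    start = list(a = a0, mu = mu0, s = s0),
    lower = c(a = 0, mu = min(x), s = atd@binWidth / 2),
    upper = c(a = Inf, mu = max(x), s = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid <- sqrt(mean(stats::residuals(fit)^2)) / cf[["a"]]
  new("GaussianFit", tD = cf[["mu"]], w05 = .fwhm * cf[["s"]],
      amplitude = cf[["a"]], goodness = resid, flagged = resid > 0.05)
}

#' Reduced mobility from a fitted drift time
#'
#' K0 = (L / (t_D E)) * (N / N0), i.e. the mobility implied by the drift
#' time, normalised to the Loschmidt density N0.
#'
#' @param tD drift time, s.
#' @param driftLength drift length, m.
#' @param gas the [GasConditions] of the measurement.
#' @return Reduced mobility, cm^2/(V s).
#' @examples
#' g <- gasConditions(1470, 353.15, 120)
#' reducedMobility(307.3e-6, 0.1505, g)   # 1.519
#' @export
reducedMobility <- function(tD, driftLength, gas) {
  if (any(tD <= 0)) stop("tD must be positive")
  K <- driftLength / (tD * gas@fieldStrength)
  K * gas@numberDensity / .N0 * 1e4
}

#' Analytic diffusion width of a nonreacting peak
#'
#' Temporal FWHM of the Fick's-law Gaussian:
#' w05_diff = 2 sqrt(2 ln 2) sqrt(2 D_L t_D) / v_d.
#'
#' @param DL longitudinal diffusion coefficient, m^2/s.
#' @param tD drift time, s.
#' @param vd drift velocity, m/s.
#' @return FWHM, s.
#' @examples
#' diffusionWidth(4.12e-4, 307.3e-6, 489.8) * 1e6   # 2.42 us
#' @export
diffusionWidth <- function(DL, tD, vd) {
  if (any(tD <= 0) || any(vd <= 0)) stop("tD and vd must be positive")
  .fwhm * sqrt(2 * DL * tD) / vd
}

#' Total peak width: diffusion convoluted with the initial pulse
#'
#' Gaussian-quadrature convolution w05 = sqrt(w05_diff^2 + w05_init^2) with
#' the initial width taken as the standard deviation of a rectangular ion
#' package created by the shutter opening time t_inj:
#' w05_init = 2 sqrt(2 ln 2) t_inj / sqrt(12).
#'
#' @param w05diff diffusion FWHM, s.
#' @param injectionTime shutter opening time t_inj, s.
#' @return Total FWHM, s.
#' @examples
#' totalWidth(2.42e-6, 3e-6) * 1e6   # 3.16 us
#' @export
totalWidth <- function(w05diff, injectionTime) {
  if (any(w05diff < 0) || any(injectionTime < 0))
    stop("widths must be >= 0")
  w05init <- .fwhm * injectionTime / sqrt(12)
  sqrt(w05diff^2 + w05init^2)
}

#' Analytic relative-peak-width curve over reduced field strength
#'
#' Evaluates the closed-form width budget w05 / t_D on an E/N grid, with the
#' longitudinal diffusion coefficient either field-dependent (generalized
#' Einstein relation) or frozen at its low-field (Einstein) value.  In the
#' constant-D mode the diffusion term falls as (E/N)^-1/2 while the
#' initial-pulse term rises as (E/N)^+1, producing a minimum; with
#' field-dependent diffusion the diffusion term itself turns over (rising as
#' (E/N)^+1/2 in the field-dominated limit), moving the minimum to lower E/N
#' and raising it.
#'
#' @param model a [MobilityModel].
#' @param gas base [GasConditions] (pressure/temperature; E/N is swept).
#' @param fields E/N grid, Td, within the mobility table range.
#' @param driftLength drift length, m.
#' @param injectionTime shutter opening time, s (0 for diffusion only).
#' @param diffusionMode `"field_dependent"` (default) or `"constant"`.
#' @return list with `curve` (data.frame: `EN_td`, `tD_s`, `w05_diff_s`,
#'   `w05_s`, `relWidth`) and `minimum` (named numeric `EN_td`, `relWidth`
#'   from grid search with parabolic refinement; the grid edge if the curve
#'   is monotone).
#' @export
relativeWidthCurve <- function(model, gas, fields, driftLength,
                               injectionTime = 3e-6,
                               diffusionMode = c("field_dependent",
                                                 "constant")) {
  diffusionMode <- match.arg(diffusionMode)
  if (any(fields <= 0)) stop("fields must be positive (Td)")
  D0 <- NULL
  if (diffusionMode == "constant") {
    gLow <- withReducedField(gas, model@k0Table[1, 1])
    D0 <- .kB * gas@temperature * mobilityAtField(model, gLow) /
      (model@charge * .e)
  }
  rows <- lapply(fields, function(f) {
    g <- withReducedField(gas, f)
    vd <- driftVelocity(model, g)
    tD <- driftLength / vd
    DL <- if (diffusionMode == "constant") D0 else
      longitudinalDiffusion(model, g)
    wd <- diffusionWidth(DL, tD, vd)
    w <- totalWidth(wd, injectionTime)
    data.frame(EN_td = f, tD_s = tD, w05_diff_s = wd, w05_s = w,
               relWidth = w / tD)
  })
  curve <- do.call(rbind, rows)
  i <- which.min(curve$relWidth)
  minimum <- c(EN_td = curve$EN_td[i], relWidth = curve$relWidth[i])
  if (i > 1 && i < nrow(curve)) {
    # parabolic refinement through the bracketing grid points
    xs <- curve$EN_td[(i - 1):(i + 1)]
    ys <- curve$relWidth[(i - 1):(i + 1)]
    p <- stats::lm(ys ~ xs + I(xs^2))$coefficients
    if (is.finite(p[3]) && p[3] > 0) {
      xv <- -p[2] / (2 * p[3])
      if (xv >= xs[1] && xv <= xs[3])
        minimum <- c(EN_td = unname(xv),
                     relWidth = unname(p[1] + p[2] * xv + p[3] * xv^2))
    }
  }
  list(curve = curve, minimum = minimum)
}

#' Log-log scaling exponent of a curve
#'
#' Least-squares slope of log(y) against log(E/N) over the requested range;
#' used to verify the analytic power-law limits of the width budget
#' (t_D ~ (E/N)^-1; w05_diff/t_D ~ (E/N)^-1/2 for constant D, ~ (E/N)^+1/2
#' field-dominated; w05_init/t_D ~ (E/N)^+1).
#'
#' @param EN reduced-field values, Td.
#' @param values curve values (must be strictly positive on the range).
#' @param range optional c(min, max) subset of EN.
#' @return Dimensionless slope.
#' @export
scalingExponent <- function(EN, values, range = NULL) {
  if (!is.null(range)) {
    keep <- EN >= range[1] & EN <= range[2]
    EN <- EN[keep]; values <- values[keep]
  }
  if (length(EN) < 2) stop("need at least two points in the fit range")
  if (any(values <= 0) || any(EN <= 0))
    stop("scaling fit requires strictly positive values")
  unname(stats::coef(stats::lm(log(values) ~ log(EN)))[2])
}

#' Assemble a 2D IMS-MS spectrum
#'
#' Histograms (arrival time, m/z of the final identity) over drift-time bins
#' and the network's m/z channels.  Distinct species sharing an m/z channel
#' (e.g. isomers) are summed into one row, matching MS observability.
#'
#' @param result an [MCResult].
#' @param network the [ReactionNetwork] providing the species -> m/z map.
#' @param binWidth drift-time bin width, s (3 us for the MS-coupled mode).
#' @param useFinal use post-transfer identities; default if extended.
#' @return A [Spectrum2D]; its sum over m/z reproduces the total ATD.
#' @export
assemble2d <- function(result, network, binWidth = 3e-6,
                       useFinal = result@extended) {
  sp <- network@species
  if (any(!is.finite(sp$mz)))
    stop("every species needs a finite m/z for a 2D spectrum")
  arr <- result@arrivals
  ids <- if (useFinal && !is.null(arr$species_final))
    arr$species_final else arr$species
  mzOf <- stats::setNames(sp$mz, sp$name)
  channels <- sort(unique(sp$mz))
  edges <- .binEdges(arr$arrival_s, binWidth)
  M <- matrix(0, length(channels), length(edges) - 1)
  for (k in seq_along(channels)) {
    sel <- mzOf[ids] == channels[k]
    if (any(sel))
      M[k, ] <- graphics::hist(arr$arrival_s[sel], breaks = edges,
                               plot = FALSE)$counts
  }
  new("Spectrum2D", driftEdges = edges, mz = channels, intensity = M)
}
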