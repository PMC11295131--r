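# ATD analysis: Gaussian fits, reduced mobility, width budgets, scaling
# exponents, 2D spectra.

test_that("a noise-free Gaussian histogram is recovered almost exactly", {
  atd <- gaussianATD(tD = 300e-6, w05 = 3e-6)
  fit <- fitGaussian(atd, "A")
  expect_equal(fit@tD, 300e-6, tolerance = 1e-6)
  expect_equal(fit@w05, 3e-6, tolerance = 1e-6)
  expect_lt(fit@goodness, 1e-8)
  expect_false(fit@flagged)
})

test_that("bimodal histograms are flagged, degenerate ones rejected", {
  a1 <- gaussianATD(tD = 300e-6, w05 = 3e-6)
  a2 <- gaussianATD(tD = 320e-6, w05 = 3e-6)
  edges <- seq(290e-6, 330e-6, by = 56e-9)
  x <- (edges[-1] + edges[-length(edges)]) / 2
  s <- 3e-6 / (2 * sqrt(2 * log(2)))
  counts <- matrix(1000 * (exp(-(x - 300e-6)^2 / (2 * s^2)) +
                             exp(-(x - 320e-6)^2 / (2 * s^2))), nrow = 1,
                   dimnames = list("A", NULL))
  bim <- new("ATDHistogram", binEdges = edges, counts = counts,
             binWidth = 56e-9)
  expect_true(fitGaussian(bim, "A")@flagged)
  # all counts in one bin
  one <- new("ATDHistogram", binEdges = edges,
             counts = matrix(c(500, rep(0, length(x) - 1)), nrow = 1,
                             dimnames = list("A", NULL)),
             binWidth = 56e-9)
  expect_error(fitGaussian(one, "A"), "degenerate")
  # too few populated bins
  few <- new("ATDHistogram", binEdges = edges,
             counts = matrix(c(1, 2, 3, rep(0, length(x) - 3)), nrow = 1,
                             dimnames = list("A", NULL)),
             binWidth = 56e-9)
  expect_error(fitGaussian(few, "A"), "5 nonzero")
})

test_that("reduced mobility inverts the drift-velocity relation", {
  g <- refGas(120)
  expect_equal(reducedMobility(307.3e-6, 0.1505, g), 1.519,
               tolerance = 1e-3)
  expect_equal(reducedMobility(2 * 307.3e-6, 0.1505, g),
               reducedMobility(307.3e-6, 0.1505, g) / 2, tolerance = 1e-12)
  # round trip through the ensemble integrator on a constant-K0 model
  net <- reactionNetwork(data.frame(name = "A", mz = 1),
                         list(A = constantModel("A", 1.519, mass = 192.2)))
  ens <- propagateEnsemble(net, g, dt = 1e-7, driftLength = 0.1505)
  expect_equal(reducedMobility(arrivalTime(ens), 0.1505, g), 1.519,
               tolerance = 1e-6)
})

test_that("width budget formulas match hand-evaluated values", {
  expect_equal(diffusionWidth(4.12e-4, 307.3e-6, 489.8), 2.42e-6,
               tolerance = 1e-3)
  expect_equal(diffusionWidth(0, 307.3e-6, 489.8), 0)
  expect_equal(diffusionWidth(4.12e-4, 4 * 307.3e-6, 489.8),
               2 * diffusionWidth(4.12e-4, 307.3e-6, 489.8),
               tolerance = 1e-12)
  expect_equal(totalWidth(2.419e-6, 3e-6), 3.164e-6, tolerance = 1e-3)
  expect_equal(totalWidth(2.42e-6, 0), 2.42e-6)
  expect_equal(totalWidth(0, 3e-6), 2.039e-6, tolerance = 1e-3)
})

test_that("nonreacting MC widths close the analytic budget across fields", {
  net <- reactionNetwork(data.frame(name = "A", mz = 192),
                         list(A = dtbpSystem()@network@mobility[[1]]))
  L <- 0.1505; tInj <- 3e-6
  for (EN in c(30, 70, 120)) {
    g <- refGas(EN)
    m <- mobilityOf(net, "A")
    vd <- driftVelocity(m, g); tD <- L / vd
    w05 <- totalWidth(diffusionWidth(longitudinalDiffusion(m, g), tD, vd),
                      tInj)
    res <- simulateMC(net, g, L,
                      mcConfig(nParticles = 4000, seed = 40 + EN,
                               initialPulse = "rectangular", tInj = tInj))
    fit <- fitGaussian(atdHistogram(res, 56e-9))
    expect_lt(abs(fit@w05 - w05), 3 * w05 / sqrt(2 * 4000))
    expect_lt(abs(fit@tD - (tD + tInj / 2)), 3 * w05 / 2.355 / sqrt(4000))
  }
})

test_that("relative-width curve has the documented shape and minimum shift", {
  b <- dtbpSystem()
  m <- mobilityOf(b@network, "DtBP_H")
  fields <- seq(10, 120, by = 2)
  cFD <- relativeWidthCurve(m, b@gas, fields, b@driftLength, 3e-6,
                            "field_dependent")
  cC <- relativeWidthCurve(m, b@gas, fields, b@driftLength, 3e-6,
                           "constant")
  # low-field segment decreases in the constant-D mode
  lowSeg <- cC$curve$relWidth[cC$curve$EN_td <= 30]
  expect_true(all(diff(lowSeg) < 0))
  # field-dependent diffusion: minimum at smaller E/N and not as low
  expect_lt(cFD$minimum[["EN_td"]], cC$minimum[["EN_td"]])
  expect_gt(cFD$minimum[["relWidth"]], cC$minimum[["relWidth"]])
  # no initial pulse, constant D: a single power law, monotone decreasing
  c0 <- relativeWidthCurve(m, b@gas, fields, b@driftLength, 0, "constant")
  expect_true(all(diff(c0$curve$relWidth) < 0))
})

test_that("scaling exponents reproduce the four analytic power laws", {
  gas <- gasConditions(1470, 353.15, 0)
  m <- mobilityModel("ion", 192.2,
                     data.frame(EN_td = c(0, 5000), K0_cm2_Vs = c(1.5, 1.5)))
  L <- 0.1505
  lowF <- seq(2, 20, by = 2)
  highF <- seq(2000, 5000, by = 250)
  cLow <- relativeWidthCurve(m, gas, lowF, L, 0, "constant")
  # drift time ~ (E/N)^-1 for a field-independent K0
  expect_equal(scalingExponent(cLow$curve$EN_td, cLow$curve$tD_s), -1,
               tolerance = 1e-9)
  # diffusion-limited, constant D: w/tD ~ (E/N)^-1/2
  expect_equal(scalingExponent(cLow$curve$EN_td, cLow$curve$relWidth), -0.5,
               tolerance = 1e-3)
  # initial-width-limited: w_init/tD ~ (E/N)^+1
  wInit <- totalWidth(0, 3e-6) / cLow$curve$tD_s
  expect_equal(scalingExponent(cLow$curve$EN_td, wInit), 1,
               tolerance = 1e-9)
  # field-dominated diffusion: w/tD ~ (E/N)^+1/2
  cHigh <- relativeWidthCurve(m, gas, highF, L, 0, "field_dependent")
  expect_equal(scalingExponent(cHigh$curve$EN_td, cHigh$curve$relWidth),
               0.5, tolerance = 1e-2)
  expect_error(scalingExponent(c(1, 2), c(1, -1)), "positive")
})

test_that("2D spectra marginalise to the total ATD", {
  b <- meohWaterSystem()
  g <- withReducedField(b@gas, 70)
  res <- simulateMC(b@network, g, b@driftLength,
                    mcConfig(nParticles = 1500, seed = 3))
  spec <- assemble2d(res, b@network, binWidth = 3e-6)
  atd <- atdHistogram(res, binWidth = 3e-6)
  expect_equal(colSums(spec@intensity), unname(colSums(atd@counts)))
  expect_equal(sum(spec@intensity), 1500)
  # single-species result: one occupied m/z row equal to the total ATD
  bd <- dtbpSystem()
  resD <- simulateMC(bd@network, withReducedField(bd@gas, 100),
                     bd@driftLength, mcConfig(nParticles = 400, seed = 4))
  specD <- assemble2d(resD, bd@network, binWidth = 3e-6)
  expect_equal(nrow(specD@intensity), 1)
  expect_equal(sum(specD@intensity), 400)
})

test_that("fast-exchange hydrates share a drift-time centroid", {
  b <- meohWaterSystem()
  g <- withReducedField(b@gas, 70)
  res <- simulateMC(b@network, g, b@driftLength,
                    mcConfig(nParticles = 3000, seed = 8))
  arr <- arrivals(res)
  cent <- vapply(c("bare", "mono", "di"), function(s)
    mean(arr$arrival_s[arr$species == s]), numeric(1))
  # span of nonreacting arrival times of the same three species
  tPure <- vapply(c("bare", "mono", "di"), function(s)
    b@driftLength / driftVelocity(mobilityOf(b@network, s), g), numeric(1))
  expect_lt(max(cent) - min(cent), 0.25 * (max(tPure) - min(tPure)))
  # while the slow proton-bound dimer arrives distinctly later
  centDimer <- mean(arr$arrival_s[arr$species == "dimer"])
  expect_gt(centDimer, max(cent[c("bare", "mono")]))
})
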