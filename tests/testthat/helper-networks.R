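# Builders for small synthetic networks and histograms used across tests.

# reference conditions used by most fixtures below: 14.7 mbar, 80 C
refGas <- function(EN = 120) gasConditions(1470, 353.15, EN)

# field-independent mobility model over a configurable range
constantModel <- function(name, k0, mass = 100, top = 200) {
  mobilityModel(name, mass,
                data.frame(EN_td = c(0, top), K0_cm2_Vs = rep(k0, 2)))
}

# invert the Eyring equation: barrier (kJ/mol) giving rate k at temperature T
barrierForRate <- function(k, Tion) {
  kB <- imsConstants()[["kB"]]; h <- imsConstants()[["h"]]
  R <- imsConstants()[["Rgas"]]
  max(-R * Tion * log(k * h / (kB * Tion)) / 1e3, 0)
}

# two species with unimolecular interconversion at prescribed rates
# (realised as tight barriers solved at each reactant's T_eff under `gas`)
twoStateNetwork <- function(kAB, kBA = 0, k0A = 1.519, k0B = 1.519,
                            gas = refGas()) {
  mobA <- constantModel("A", k0A)
  mobB <- constantModel("B", k0B)
  rx <- list()
  if (kAB > 0)
    rx[[length(rx) + 1]] <- list(
      reactant = "A", product = "B", kind = "tight",
      barrier = barrierForRate(kAB, effectiveTemperature(mobA, gas)))
  if (kBA > 0)
    rx[[length(rx) + 1]] <- list(
      reactant = "B", product = "A", kind = "tight",
      barrier = barrierForRate(kBA, effectiveTemperature(mobB, gas)))
  reactionNetwork(data.frame(name = c("A", "B"), mz = c(100, 120)),
                  list(A = mobA, B = mobB), rx)
}

# reversible cluster pair: ion + neutral <-> cluster, equal mobilities so
# both directions see the same effective temperature
assocPairNetwork <- function(dG, c0, k0 = 2.0, dipole = 0,
                             lengthScale = NA) {
  prof <- if (is.na(lengthScale)) neutralProfile("constant", c0) else
    neutralProfile("exponential_decay", c0, lengthScale)
  nu <- list(name = "X", mass = 18, polarizability = 1.45, dipole = dipole,
             profile = prof)
  reactionNetwork(
    data.frame(name = c("ion", "cluster"), mz = c(50, 68)),
    list(ion = constantModel("ion", k0), cluster = constantModel("cluster", k0)),
    list(list(reactant = "ion", product = "cluster",
              kind = "loose_association", dGassoc = dG, neutral = nu)))
}

# noise-free Gaussian histogram (counts evaluated at bin centres)
gaussianATD <- function(tD = 300e-6, w05 = 3e-6, binWidth = 56e-9,
                        amplitude = 1000, species = "A") {
  s <- w05 / (2 * sqrt(2 * log(2)))
  edges <- seq(tD - 6 * s, tD + 6 * s, by = binWidth)
  x <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- matrix(amplitude * exp(-(x - tD)^2 / (2 * s^2)), nrow = 1,
                   dimnames = list(species, NULL))
  new("ATDHistogram", binEdges = edges, counts = counts,
      binWidth = binWidth)
}

# stationary distribution of a rate matrix via its null space
stationaryOf <- function(R) {
  eig <- eigen(R)
  v <- abs(Re(eig$vectors[, which.min(abs(eig$values))]))
  v / sum(v)
}
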