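# Kinetics: Eyring and capture rates, detailed-balance closure, rate
# matrices and the column-stochastic transition matrix.

test_that("Eyring rates match hand-evaluated values and monotonicity", {
  expect_equal(eyringRate(133.5, 600), 29.85, tolerance = 1e-3)
  kB <- imsConstants()[["kB"]]; h <- imsConstants()[["h"]]
  expect_equal(eyringRate(0, 600), kB * 600 / h, tolerance = 1e-12)
  # barrier-difference ratio exp(-3.0 / (R T))
  R <- imsConstants()[["Rgas"]]
  expect_equal(eyringRate(136.5, 600) / eyringRate(133.5, 600),
               exp(-3.0e3 / (R * 600)), tolerance = 1e-12)
  # strictly increasing in T, strictly decreasing in barrier
  Ts <- seq(300, 1200, by = 50)
  expect_true(all(diff(eyringRate(150, Ts)) > 0))
  bs <- seq(50, 250, by = 10)
  expect_true(all(diff(eyringRate(bs, 700)) < 0))
  expect_error(eyringRate(-1, 600), "barrier")
})

test_that("capture rate reproduces the Langevin value and dipole bounds", {
  # Langevin: 2.342e-9 sqrt(alpha/mu) cm^3/s for alpha in A^3, mu in u
  kL <- captureRate(1.45, 0, 11.65)
  expect_equal(kL * 1e6, 2.342e-9 * sqrt(1.45 / 11.65), tolerance = 1e-3)
  # temperature independence without a dipole
  expect_identical(captureRate(1.45, 0, 11.65, 300),
                   captureRate(1.45, 0, 11.65, 1200))
  # locking enhancement is >= 1 and decreases with temperature
  k300 <- captureRate(1.45, 1.85, 11.65, 300)
  k1200 <- captureRate(1.45, 1.85, 11.65, 1200)
  expect_gt(k300, kL)
  expect_gt(k1200, kL)
  expect_gt(k300, k1200)
})

test_that("detailed-balance dissociation rate gives the Boltzmann ratio", {
  N0 <- imsConstants()[["N0"]]
  kf <- 8.26e-16
  # dG = 0 at standard concentration: k_r = k_f c
  expect_equal(dissociationRate(kf, 0, 600, N0), kf * N0,
               tolerance = 1e-12)
  # the ratio k_f c / k_r equals the pseudo-first-order K_eq for any triple
  R <- imsConstants()[["Rgas"]]
  for (dG in c(-60, -10, 5)) for (c0 in c(1e18, 1e20)) {
    kr <- dissociationRate(kf, dG, 700, c0)
    Keq <- (c0 / N0) * exp(-dG * 1e3 / (R * 700))
    expect_equal(kf * c0 / kr, Keq, tolerance = 1e-12)
  }
})

test_that("an isolated cluster pair relaxes to the Boltzmann ratio, against an ODE oracle", {
  skip_if_not_installed("deSolve")
  R <- imsConstants()[["Rgas"]]; N0 <- imsConstants()[["N0"]]
  set.seed(42)
  for (i in 1:100) {
    dG <- runif(1, -60, -20)
    c0 <- 10^runif(1, 18, 20)
    net <- assocPairNetwork(dG, c0)
    gas <- refGas(runif(1, 40, 110))
    Rm <- buildRateMatrix(net, gas)
    Teff <- effectiveTemperature(mobilityOf(net, "ion"), gas)
    Keq <- (c0 / N0) * exp(-dG * 1e3 / (R * Teff))
    # stationary distribution of the generator
    st <- stationaryOf(Rm)
    expect_equal(st[2] / st[1], Keq, tolerance = 1e-8)
    # brute-force integration to stationarity (independent oracle)
    tEq <- 20 / max(abs(diag(Rm)))
    ode <- deSolve::lsoda(c(1, 0), c(0, tEq),
                          function(t, y, p) list(as.numeric(Rm %*% y)),
                          NULL, rtol = 1e-10, atol = 1e-12)
    pOde <- ode[nrow(ode), -1]
    expect_equal(unname(pOde[2] / pOde[1]), Keq, tolerance = 1e-4)
  }
})

test_that("rate matrices have the documented structure", {
  # single irreversible reaction A -> B at 1000 /s
  gas <- refGas(120)
  net <- twoStateNetwork(1000, 0, gas = gas)
  Rm <- buildRateMatrix(net, gas)
  expect_equal(unname(Rm), matrix(c(-1000, 1000, 0, 0), 2, 2),
               tolerance = 1e-6)
  expect_equal(colSums(Rm), c(A = 0, B = 0), tolerance = 1e-9)
  # empty reaction list -> zero matrix
  netEmpty <- reactionNetwork(data.frame(name = "A", mz = 1),
                              list(A = constantModel("A", 2)))
  expect_equal(unname(buildRateMatrix(netEmpty, gas)), matrix(0, 1, 1))
  # exponential neutral profile: rates fall by 1/e per length scale
  netP <- assocPairNetwork(-60, 1e19, lengthScale = 0.05)
  R0 <- buildRateMatrix(netP, gas, position = 0)
  R1 <- buildRateMatrix(netP, gas, position = 0.05)
  expect_equal(R1[2, 1] / R0[2, 1], exp(-1), tolerance = 1e-12)
  # dissociation rate is independent of the local neutral density
  expect_equal(R1[1, 2], R0[1, 2], tolerance = 1e-12)
})

test_that("neutral concentration profiles evaluate as declared", {
  pc <- neutralProfile("constant", 1e18)
  expect_equal(neutralConcentration(pc, c(0, 0.1)), rep(1e18, 2))
  pd <- neutralProfile("exponential_decay", 1e18, 0.05)
  expect_equal(neutralConcentration(pd, 0), 1e18)
  expect_equal(neutralConcentration(pd, 0.05), 1e18 / exp(1))
  expect_error(neutralConcentration(pd, -0.01), "position")
})

test_that("transition matrix is the exact exponential and column-stochastic", {
  gas <- refGas(120)
  net <- twoStateNetwork(1000, 0, gas = gas)
  Rm <- buildRateMatrix(net, gas)
  phi <- phiMatrix(transitionMatrix(Rm, 1e-6))
  expect_equal(phi[2, 1], 1 - exp(-1e-3), tolerance = 1e-9)
  # zero rates give the identity
  expect_equal(phiMatrix(transitionMatrix(matrix(0, 3, 3), 1e-5)), diag(3))
  # columns sum to one and the semigroup property holds
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    M <- matrix(runif(n * n) * 1e4, n, n)
    diag(M) <- 0
    diag(M) <- -colSums(M)
    dt <- 0.04 / max(-diag(M))
    phi1 <- phiMatrix(transitionMatrix(M, dt))
    expect_true(all(abs(colSums(phi1) - 1) < 1e-12))
    expect_true(all(phi1 >= 0 & phi1 <= 1))
    phi2 <- phiMatrix(transitionMatrix(M, 2 * dt, check = FALSE))
    expect_equal(phi1 %*% phi1, phi2, tolerance = 1e-10)
  }
})

test_that("the step-size guard rejects too-large dt with advice", {
  gas <- refGas(120)
  net <- twoStateNetwork(5e4, 0, gas = gas)
  Rm <- buildRateMatrix(net, gas)
  expect_error(transitionMatrix(Rm, 1e-4), "reduce dt")
  expect_silent(transitionMatrix(Rm, 1e-6))
  # suggestTimestep respects both the guard and the ATD resolution
  dt <- suggestTimestep(net, gas, 0.1505)
  expect_silent(transitionMatrix(Rm, dt))
  netSlow <- twoStateNetwork(10, 0, gas = gas)
  tD <- 0.1505 / driftVelocity(mobilityOf(netSlow, "A"), gas)
  expect_equal(suggestTimestep(netSlow, gas, 0.1505), tD / 500,
               tolerance = 1e-9)
})

test_that("population is conserved under repeated transition steps", {
  gas <- refGas(100)
  net <- assocPairNetwork(-50, 1e19)
  dt <- suggestTimestep(net, gas, 0.1505)
  phi <- phiMatrix(transitionMatrix(buildRateMatrix(net, gas), dt))
  P <- c(0.3, 0.7)
  for (i in 1:500) P <- phi %*% P
  expect_equal(sum(P), 1, tolerance = 1e-12)
})
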