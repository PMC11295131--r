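# Propagation: ensemble Markov-chain integrator, particle Monte Carlo
# engine, transfer-region extension, field scans.

test_that("ensemble arrival time matches the closed form for one species", {
  gas <- refGas(120)
  net <- reactionNetwork(data.frame(name = "A", mz = 100),
                         list(A = constantModel("A", 1.519, mass = 192.2)))
  L <- 0.1505
  tD <- L / driftVelocity(mobilityOf(net, "A"), gas)   # 307.3 us
  expect_equal(tD, 307.3e-6, tolerance = 1e-3)
  ens <- propagateEnsemble(net, gas, driftLength = L)
  expect_equal(arrivalTime(ens), tD, tolerance = 2e-3)
  # populations stay normalised at every recorded step
  traj <- trajectory(ens)
  expect_true(all(abs(traj$A - 1) < 1e-12))
})

test_that("ensemble drift velocity is the population-weighted mean", {
  gas <- refGas(100)
  mobA <- constantModel("A", 1.0)
  mobB <- constantModel("B", 2.0)
  net <- reactionNetwork(data.frame(name = c("A", "B"), mz = c(1, 2)),
                         list(A = mobA, B = mobB))
  L <- 0.1505
  ens <- propagateEnsemble(net, gas, driftLength = L,
                           initialPopulations = c(A = 0.5, B = 0.5))
  vMean <- 1.5 * driftVelocity(mobA, gas)
  expect_equal(arrivalTime(ens), L / vMean, tolerance = 2e-3)
  traj <- trajectory(ens)
  expect_true(all(abs(traj$A + traj$B - 1) < 1e-10))
  expect_true(all(diff(traj$position_m) > 0))
})

test_that("a single MC step has the documented drift and diffusion parts", {
  phiId <- transitionMatrix(matrix(0, 2, 2,
                                   dimnames = list(c("A", "B"), c("A", "B"))),
                            1e-6)
  v <- c(A = 500, B = 250); D0 <- c(A = 0, B = 0)
  set.seed(1)
  p <- list(species = "A", position = 0, clock = 0, events = numeric())
  p1 <- mcStep(p, phiId, v, D0, 1e-6)
  expect_equal(p1$position, 500e-6, tolerance = 1e-12)  # pure drift
  expect_equal(p1$clock, 1e-6)
  expect_identical(p1$species, "A")
  # pure random walk: |step| = sqrt(2 D dt) exactly, zero-mean over many
  D1 <- c(A = 4e-4, B = 4e-4); v0 <- c(A = 0, B = 0)
  set.seed(2)
  steps <- replicate(400, {
    q <- mcStep(p, phiId, v0, D1, 1e-6)
    q$position
  })
  expect_true(all(abs(abs(steps) - sqrt(2 * 4e-4 * 1e-6)) < 1e-15))
  expect_lt(abs(mean(steps)), 5 * sqrt(2 * 4e-4 * 1e-6) / sqrt(400))
})

test_that("random-walk displacement variance grows as 2 D t", {
  # 200 walkers x 500 steps via the compiled engine in fixed-time mode
  gas <- refGas(0)   # no drift
  D <- 4e-4; dt <- 1e-6; n <- 500
  # recover positions from arrival-free walk: use mcStep chains instead
  set.seed(3)
  phiId <- transitionMatrix(matrix(0, 1, 1, dimnames = list("A", "A")), dt)
  finals <- replicate(200, {
    p <- list(species = "A", position = 0, clock = 0, events = numeric())
    for (i in seq_len(n))
      p <- mcStep(p, phiId, c(A = 0), c(A = D), dt)
    p$position
  })
  v <- stats::var(finals)
  expected <- 2 * D * n * dt
  # variance of the sample variance: relative SE ~ sqrt(2/(N-1))
  expect_lt(abs(v - expected) / expected, 3 * sqrt(2 / 199))
})

test_that("MC arrival statistics match the Fick's-law closed form", {
  gas <- refGas(120)
  net <- reactionNetwork(data.frame(name = "A", mz = 100),
                         list(A = constantModel("A", 1.519, mass = 192.2)))
  L <- 0.1505
  m <- mobilityOf(net, "A")
  vd <- driftVelocity(m, gas); tD <- L / vd
  DL <- longitudinalDiffusion(m, gas)
  res <- simulateMC(net, gas, L, mcConfig(nParticles = 4000, seed = 11))
  arr <- arrivals(res)$arrival_s
  expect_equal(length(arr), 4000)                      # every particle lands
  sigma <- sqrt(2 * DL * tD) / vd
  expect_lt(abs(mean(arr) - tD), 3 * sigma / sqrt(4000))
  expect_lt(abs(sd(arr) - sigma) / sigma, 3 * sqrt(1 / (2 * 4000)) + 0.02)
  # shape: quartiles of a Gaussian
  q <- quantile(arr, c(0.25, 0.75))
  expect_equal(unname(diff(q)) / sigma, 2 * qnorm(0.75), tolerance = 0.1)
})

test_that("irreversible decay leaves the closed-form parent survival", {
  gas <- refGas(120)
  net <- twoStateNetwork(3000, 0, gas = gas)
  L <- 0.1505
  tD <- L / driftVelocity(mobilityOf(net, "A"), gas)
  res <- simulateMC(net, gas, L, mcConfig(nParticles = 4000, seed = 5))
  pA <- finalPopulations(res)[["A"]]
  surv <- exp(-3000 * tD)                              # 0.398
  expect_equal(surv, 0.398, tolerance = 1e-3)
  expect_lt(abs(pA - surv), 3 * sqrt(surv * (1 - surv) / 4000))
  # event bookkeeping: one A->B event per converted particle
  expect_equal(eventCounts(res)[["A->B"]], 1 - pA, tolerance = 0.02)
})

test_that("MC results are bit-identical for a fixed seed", {
  b <- dtbpSystem()
  g <- withReducedField(b@gas, 100)
  cfg <- mcConfig(nParticles = 300, seed = 123)
  r1 <- simulateMC(b@network, g, b@driftLength, cfg)
  r2 <- simulateMC(b@network, g, b@driftLength, cfg)
  expect_identical(arrivals(r1), arrivals(r2))
  r3 <- simulateMC(b@network, g, b@driftLength,
                   mcConfig(nParticles = 300, seed = 124))
  expect_false(identical(arrivals(r1)$arrival_s, arrivals(r3)$arrival_s))
})

test_that("halving the time step moves mean arrivals by less than 0.1 %", {
  gas <- refGas(120)
  net <- twoStateNetwork(3000, 1000, k0B = 2.0, gas = gas)
  L <- 0.1505
  dt0 <- suggestTimestep(net, gas, L)
  a1 <- arrivals(simulateMC(net, gas, L,
    mcConfig(nParticles = 3000, seed = 9, dt = dt0)))$arrival_s
  a2 <- arrivals(simulateMC(net, gas, L,
    mcConfig(nParticles = 3000, seed = 9, dt = dt0 / 2)))$arrival_s
  seDiff <- sqrt(var(a1) / length(a1) + var(a2) / length(a2))
  expect_lt(abs(mean(a1) - mean(a2)), 1e-3 * mean(a1) + 3 * seDiff)
})

test_that("fast exchange converges to the ensemble-mobility arrival time", {
  gas <- refGas(100)
  L <- 0.1505
  mobA <- constantModel("A", 1.2); mobB <- constantModel("B", 2.4)
  tDscale <- L / driftVelocity(mobA, gas)
  kf <- 300 / tDscale; kb <- 150 / tDscale
  net <- twoStateNetwork(kf, kb, k0A = 1.2, k0B = 2.4, gas = gas)
  Peq <- stationaryOf(buildRateMatrix(net, gas))
  vEns <- Peq[1] * driftVelocity(mobA, gas) + Peq[2] * driftVelocity(mobB, gas)
  res <- simulateMC(net, gas, L, mcConfig(nParticles = 2000, seed = 21),
                    initialPopulations = c(A = Peq[1], B = Peq[2]))
  arr <- arrivals(res)$arrival_s
  expect_lt(abs(mean(arr) - L / vEns), 3 * sd(arr) / sqrt(2000))
  # merged peak: unimodal, narrow relative to the A-B arrival split
  split <- L / driftVelocity(mobA, gas) - L / driftVelocity(mobB, gas)
  expect_lt(sd(arr), 0.2 * split)
})

test_that("slow exchange resolves two peaks at the pure-species arrivals", {
  gas <- refGas(100)
  L <- 0.1505
  net <- twoStateNetwork(1, 1, k0A = 1.2, k0B = 2.4, gas = gas)
  tA <- L / driftVelocity(mobilityOf(net, "A"), gas)
  tB <- L / driftVelocity(mobilityOf(net, "B"), gas)
  res <- simulateMC(net, gas, L, mcConfig(nParticles = 1000, seed = 31),
                    initialPopulations = c(A = 0.5, B = 0.5))
  arr <- arrivals(res)
  tol <- 0.05 * (tA - tB)
  nearA <- abs(arr$arrival_s - tA) < tol
  nearB <- abs(arr$arrival_s - tB) < tol
  expect_gt(mean(nearA | nearB), 0.98)       # two resolved peaks
  expect_gt(mean(nearA), 0.4)
  expect_gt(mean(nearB), 0.4)
  expect_equal(mean(arr$arrival_s[nearA]), tA, tolerance = 1e-3)
  expect_equal(mean(arr$arrival_s[nearB]), tB, tolerance = 1e-3)
})

test_that("MC identity fractions track ensemble populations at fixed time", {
  # cross-engine check on a handful of random networks (the acceptance
  # suite runs the full 100-network version)
  for (seed in 1:5) {
    b <- randomScenario(seed, regime = "fast")
    gas <- b@gas
    dt <- suggestTimestep(b@network, gas, b@driftLength)
    tObs <- b@reference$tD * 0.3
    np <- 400
    res <- simulateMC(b@network, gas, b@driftLength,
                      mcConfig(nParticles = np, seed = seed, dt = dt,
                               tMax = tObs))
    ens <- propagateEnsemble(b@network, gas, dt = dt,
                             driftLength = b@driftLength, maxTime = tObs)
    pens <- finalPopulations(ens)
    pmc <- finalPopulations(res)
    tol <- 3 * sqrt(pmax(pens * (1 - pens), 0.25 / np) / np)
    expect_true(all(abs(pmc - pens) <= tol + 0.02))
  }
})

test_that("ensemble populations match the bundled ODE reference", {
  for (seed in c(2, 5, 8)) {
    b <- randomScenario(seed, regime = "mixed")
    dt <- suggestTimestep(b@network, b@gas, b@driftLength)
    tObs <- b@reference$tD * 0.2
    ens <- propagateEnsemble(b@network, b@gas, dt = dt,
                             driftLength = b@driftLength, maxTime = tObs)
    tEnd <- trajectory(ens)$time_s[nrow(trajectory(ens))]
    ref <- b@reference$populations(tEnd)
    expect_equal(unname(finalPopulations(ens)), ref, tolerance = 1e-6)
  }
})

test_that("transfer-region extension follows the exponential closed form", {
  gas <- refGas(120)
  net <- twoStateNetwork(3000, 0, gas = gas)
  L <- 0.1505
  res <- simulateMC(net, gas, L, mcConfig(nParticles = 4000, seed = 13))
  # zero transfer time: identities unchanged
  ext0 <- extendTransferRegion(res, net, transferTime = 0)
  expect_identical(arrivals(ext0)$species_final, arrivals(ext0)$species)
  # 50 us of further first-order decay multiplies survivors by exp(-0.15)
  ext <- extendTransferRegion(res, net, transferTime = 50e-6)
  pBefore <- finalPopulations(res)[["A"]]
  pAfter <- finalPopulations(ext)[["A"]]
  fac <- exp(-3000 * 50e-6)
  expect_equal(fac, 0.861, tolerance = 1e-3)
  expect_lt(abs(pAfter / pBefore - fac),
            3 * sqrt(fac * (1 - fac) / (4000 * pBefore)))
  expect_true(ext@extended)
  # arrival times are untouched
  expect_identical(arrivals(ext)$arrival_s, arrivals(res)$arrival_s)
})

test_that("an equilibrated system is left unchanged by the transfer region", {
  gas <- refGas(100)
  L <- 0.1505
  tDscale <- L / driftVelocity(constantModel("A", 1.5), gas)
  net <- twoStateNetwork(500 / tDscale, 250 / tDscale, k0A = 1.5,
                         k0B = 1.5, gas = gas)
  Peq <- stationaryOf(buildRateMatrix(net, gas))
  res <- simulateMC(net, gas, L, mcConfig(nParticles = 2000, seed = 17),
                    initialPopulations = c(A = Peq[1], B = Peq[2]))
  ext <- extendTransferRegion(res, net, transferTime = 50e-6)
  dP <- abs(finalPopulations(ext) - finalPopulations(res))
  expect_true(all(dP < 3 * sqrt(0.25 / 2000) + 0.02))
})

test_that("field scans report fractions per grid point and stage", {
  b <- dtbpSystem()
  tab <- fieldScan(b@network, b@gas, c(40, 80, 120),
                   driftLength = b@driftLength)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$fraction == 1))       # nonreacting species
  expect_true(all(tab$stage == "drift"))
})

test_that("runaway propagation is caught by the step cap", {
  gas <- refGas(120)
  net <- reactionNetwork(data.frame(name = "A", mz = 1),
                         list(A = constantModel("A", 1.5)))
  expect_error(simulateMC(net, gas, 0.1505,
                          mcConfig(nParticles = 10, seed = 1,
                                   maxSteps = 10)),
               "step cap")
})
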