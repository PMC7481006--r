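test_that("generators are bitwise deterministic under a fixed seed", {
  c1 <- inVivoSimConfig(duration = 15, juxtaRate = 2000, kappa = 1,
                        seed = 103)
  s1 <- simulateInVivo(c1)
  s2 <- simulateInVivo(c1)
  expect_identical(samples(s1$lfp), samples(s2$lfp))
  expect_identical(samples(s1$juxta), samples(s2$juxta))
  expect_identical(s1$truth$spikeTimes, s2$truth$spikeTimes)

  n1 <- simulateCurrentSteps(neuronSimConfig(seed = 5))
  n2 <- simulateCurrentSteps(neuronSimConfig(seed = 5))
  expect_identical(samples(n1$sweeps@traces[[3]]),
                   samples(n2$sweeps@traces[[3]]))

  q1 <- simulateSynapticTrains(synapseSimConfig(nSweeps = 5, seed = 5))
  q2 <- simulateSynapticTrains(synapseSimConfig(nSweeps = 5, seed = 5))
  expect_identical(samples(q1$recording@sweeps[[5]]),
                   samples(q2$recording@sweeps[[5]]))
})

test_that("state-conditional spike counts match Poisson expectations", {
  cfg <- inVivoSimConfig(duration = 600, juxtaRate = 1000,
                         spikeRateUp = 4, spikeRateDown = 0.2, seed = 107)
  sim <- simulateInVivo(cfg)
  states <- sim$truth$states
  upTime <- sum(states$end[states$label == "UP"] -
                states$start[states$label == "UP"])
  downTime <- cfg$duration - upTime
  st <- sim$truth$spikeTimes
  inUp <- vapply(st, function(t)
    any(states$label == "UP" & states$start <= t & states$end > t),
    logical(1))
  nUp <- sum(inUp); nDown <- sum(!inUp)
  expect_lt(abs(nUp - 4 * upTime), 3 * sqrt(4 * upTime))
  expect_lt(abs(nDown - 0.2 * downTime), 3 * sqrt(0.2 * downTime) + 3)
})

test_that("kappa = 0 gives uniform phases and near-zero PPC downstream", {
  sim <- simulateInVivo(inVivoSimConfig(duration = 300, juxtaRate = 1000,
                                        spikeRateUp = 4, spikeRateDown = 0.5,
                                        kappa = 0, seed = 109))
  tab <- bandPPC(lowpass(sim$lfp, 100), sim$spikes,
                 bands = list(c(20, 40)))
  expect_lt(abs(tab$ppc), 0.01)
})

test_that("coupled spike phases reject uniformity (Rayleigh) and fit the oracle", {
  set.seed(113)
  ph <- rVonMises(1000, 0.5, 2)
  n <- length(ph)
  R <- Mod(mean(exp(1i * ph)))
  rayleighP <- exp(-n * R^2)   # large-sample Rayleigh tail
  expect_lt(rayleighP, 1e-6)
  expect_lt(abs(mean(cos(ph - 0.5)) - besselI(2, 1) / besselI(2, 0)), 0.05)
})

test_that("state durations respect the truncation floor", {
  sim <- simulateInVivo(inVivoSimConfig(duration = 120, juxtaRate = 1000,
                                        seed = 127))
  states <- sim$truth$states
  durs <- states$end - states$start
  ## all but the (possibly clipped) final state respect the 80 ms floor
  expect_true(all(durs[-length(durs)] >= 0.080 - 1e-9))
  expect_true(all(states$label[-1] != states$label[-nrow(states)]))
})

test_that("the LIF model obeys Ohm's law and its closed-form rheobase", {
  cfg <- neuronSimConfig(model = "lif", R = 200, tauMs = 30,
                         currents = seq(50, 400, by = 25), seed = 11)
  sim <- simulateCurrentSteps(cfg)
  ## -25 pA: steady-state deflection -5 mV
  i <- which(sim$sweeps@currents == -25)
  tr <- sim$sweeps@traces[[i]]
  fs <- samplingRate(tr)
  ss <- mean(samples(tr)[round(2.0 * fs):round(2.45 * fs)])
  expect_equal(ss - cfg$vRest, -5, tolerance = 0.05)
  ## analytic rheobase (vThr - vRest)/R = 125 pA: recovered within one step
  fit <- fiFit(sim$sweeps)
  expect_lt(abs(fit@rheobase - sim$truth$rheobase), 25)
})

test_that("the rate model is silent at rheobase", {
  sim <- simulateCurrentSteps(neuronSimConfig(gain = 150, rheobase = 100,
                                              currents = c(50, 100, 150, 200,
                                                           250, 300),
                                              seed = 13))
  i <- which(sim$sweeps@currents == 100)
  expect_equal(nSpikes(detectSpikes(sim$sweeps@traces[[i]])), 0)
})

test_that("release probability extremes behave as expected", {
  s0 <- simulateSynapticTrains(synapseSimConfig(pRelease = 0, nSweeps = 12,
                                                noiseSd = 1, seed = 17))
  st0 <- analyzeTrain(s0$recording)
  expect_equal(st0@failureRate, rep(1, 5))
  s1 <- simulateSynapticTrains(synapseSimConfig(pRelease = 1, nSweeps = 12,
                                                noiseSd = 1, seed = 19))
  st1 <- analyzeTrain(s1$recording)
  expect_equal(st1@failureRate, rep(0, 5))
})

test_that("configs validate their physical constraints", {
  expect_error(inVivoSimConfig(couplingBand = c(400, 600)), "Nyquist")
  expect_error(inVivoSimConfig(kappa = -1), "non-negative")
  expect_error(inVivoSimConfig(durationFloorMs = 10), "floor")
})
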