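## A minimal noiseless deterministic recording built from the simulator.
detTrain <- function(...) {
  simulateSynapticTrains(synapseSimConfig(nSweeps = 12, noiseSd = 0,
                                          pRelease = 1, ...))
}

test_that("charge of a noiseless exponential PSC equals amplitude x tau", {
  ## hand-built pure single-exponential PSC, amplitude 100 pA, tau 15 ms
  fs <- 10000
  tt <- (seq_len(0.6 * fs) - 1) / fs
  stim <- 0.1
  y <- ifelse(tt >= stim, -100 * exp(-(tt - stim) / 0.015), 0)
  sweeps <- replicate(12, Trace(y, fs, "pA", "intracellular_I"),
                      simplify = FALSE)
  rec <- PairedTrainRecording(sweeps, stim, baselineWindow = c(0, 0.095),
                              polarity = "inward")
  st <- analyzeTrain(rec)
  ## analytic integral A * tau = 100 pA * 15 ms = 1.5 pC
  expect_lt(abs(st@q - 1.5) / 1.5, 0.02)
  expect_equal(st@failureRate, 0)
  expect_lt(abs(st@decayTau - 15) / 15, 0.05)
})

test_that("the first-pulse amplitude matches the quantal content", {
  sim <- detTrain(nSites = 1, q = 100, pscRiseMs = 0.8, pscDecayMs = 15,
                  sweepDuration = 0.6, seed = 1)
  st <- analyzeTrain(sim$recording)
  expect_lt(abs(st@amp[1] - 100) / 100, 0.01)
  expect_lt(abs(st@decayTau - 15) / 15, 0.05)
})

test_that("failure rates are per-pulse trial proportions", {
  sim <- detTrain(nSites = 1, q = 50, seed = 2)
  rec <- sim$recording
  ## erase the response in sweeps 1 and 4 of pulse 1: failure_rate = 2/12
  fs <- samplingRate(rec@sweeps[[1]])
  stim1 <- rec@stimTimes[1]
  win <- (round((stim1 - 0.002) * fs)):(round((stim1 + 0.019) * fs))
  for (sw in c(1, 4)) {
    v <- samples(rec@sweeps[[sw]])
    v[win] <- 0
    rec@sweeps[[sw]] <- Trace(v, fs, "pA", "intracellular_I")
  }
  ## tiny noise so the failure criterion has a finite scale
  set.seed(3)
  rec@sweeps <- lapply(rec@sweeps, function(tr)
    Trace(samples(tr) + rnorm(length(samples(tr)), sd = 0.5), fs, "pA",
          "intracellular_I"))
  st <- analyzeTrain(rec)
  expect_equal(st@failureRate[1], 2 / 12)
})

test_that("quantal failures and amplitude match binomial expectations", {
  p <- 0.8; nSites <- 5; q <- 20; nSweeps <- 100
  sim <- simulateSynapticTrains(synapseSimConfig(
    nSites = nSites, pRelease = p, q = q, nSweeps = nSweeps, noiseSd = 2,
    seed = 11))
  st <- analyzeTrain(sim$recording)
  pFail <- (1 - p)^nSites
  ci <- qbinom(c(0.025, 0.975), nSweeps, pFail) / nSweeps
  expect_gte(st@failureRate[1], ci[1])
  expect_lte(st@failureRate[1], ci[2])
  expect_lt(abs(st@amp[1] - nSites * p * q) / (nSites * p * q), 0.1)
})

test_that("failure rate converges to (1-p)^n on the quantal simulator", {
  p <- 0.5; nSites <- 3; nSweeps <- 1000
  sim <- simulateSynapticTrains(synapseSimConfig(
    nSites = nSites, pRelease = p, q = 30, nSweeps = nSweeps, noiseSd = 2,
    seed = 21))
  st <- analyzeTrain(sim$recording)
  pFail <- (1 - p)^nSites
  se <- sqrt(pFail * (1 - pFail) / nSweeps)
  expect_lt(abs(st@failureRate[1] - pFail), 3 * se)
})

test_that("analysis is invariant to baseline offset and polarity mirroring", {
  sim <- simulateSynapticTrains(synapseSimConfig(nSweeps = 30, seed = 5))
  st <- analyzeTrain(sim$recording)
  fs <- samplingRate(sim$recording@sweeps[[1]])
  ## constant offset
  recOff <- sim$recording
  recOff@sweeps <- lapply(recOff@sweeps, function(tr)
    Trace(samples(tr) - 37.5, fs, "pA", "intracellular_I"))
  stOff <- analyzeTrain(recOff)
  expect_equal(stOff@amp, st@amp, tolerance = 1e-9)
  expect_equal(stOff@failureRate, st@failureRate)
  expect_equal(stOff@q, st@q, tolerance = 1e-9)
  ## mirrored polarity
  recMir <- sim$recording
  recMir@sweeps <- lapply(recMir@sweeps, function(tr)
    Trace(-samples(tr), fs, "pA", "intracellular_I"))
  recMir@polarity <- "outward"
  stMir <- analyzeTrain(recMir)
  expect_equal(stMir@amp, st@amp, tolerance = 1e-9)
  expect_equal(stMir@failureRate, st@failureRate)
  expect_equal(stMir@q, st@q, tolerance = 1e-9)
})

test_that("charge is additive: doubling the currents doubles Q", {
  sim <- simulateSynapticTrains(synapseSimConfig(nSweeps = 20, seed = 6))
  st <- analyzeTrain(sim$recording)
  fs <- samplingRate(sim$recording@sweeps[[1]])
  rec2 <- sim$recording
  rec2@sweeps <- lapply(rec2@sweeps, function(tr)
    Trace(2 * samples(tr), fs, "pA", "intracellular_I"))
  st2 <- analyzeTrain(rec2)
  expect_equal(st2@q, 2 * st@q, tolerance = 1e-9)
})

test_that("STP profiles classify depression and facilitation", {
  sim <- detTrain(seed = 7)
  st <- sim |> getElement("recording") |> analyzeTrain()
  st@amp <- c(100, 60, 50, 45, 40)
  prof <- stpProfile(st)
  expect_equal(prof$ratios, c(1, .6, .5, .45, .4))
  expect_equal(prof$classification, "depressing")
  st@amp <- c(10, 15, 20, 22, 25)
  expect_equal(stpProfile(st)$classification, "facilitating")
})

test_that("depressing-train ratios follow the resource recursion", {
  U <- 0.5; tauRec <- 0.2
  sim <- simulateSynapticTrains(synapseSimConfig(
    nSweeps = 1000, noiseSd = 1,
    plasticity = list(type = "depression", U = U, tauRecMs = 200),
    seed = 13))
  st <- analyzeTrain(sim$recording)
  expected <- depressionRatios(U, tauRec)
  expect_equal(expected, sim$truth$ampRatios, tolerance = 1e-12)
  expect_lt(max(abs(st@stpRatio - expected)), 0.02)
  expect_equal(stpProfile(st)$classification, "depressing")
})

test_that("block fraction is the percent drop of the first-pulse amplitude", {
  sim <- detTrain(seed = 8)
  ctrl <- analyzeTrain(sim$recording)
  drug <- ctrl
  ctrl@amp <- c(100, 80, 70, 60, 50)
  drug@amp <- c(59, 50, 45, 40, 35)
  expect_equal(blockFraction(ctrl, drug), 41)
  expect_equal(blockFraction(ctrl, ctrl), 0)
  drug@amp <- rep(0, 5)
  expect_equal(blockFraction(ctrl, drug), 100)
  ctrl@amp <- c(0, 0, 0, 0, 0)
  expect_error(blockFraction(ctrl, drug), "positive")
})

test_that("all-failure first pulses flag the amplitude as undefined", {
  sim <- simulateSynapticTrains(synapseSimConfig(
    pRelease = 0, nSweeps = 15, noiseSd = 2, seed = 9))
  st <- analyzeTrain(sim$recording)
  expect_equal(st@failureRate[1], 1)
  expect_true(is.na(st@amp[1]))
  expect_error(stpProfile(st), "undefined")
})
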