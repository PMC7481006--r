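test_that("threshold spike detection honors crossings, peaks and refractoriness", {
  fs <- 20000
  flat <- Trace(rep(-70, fs), fs, "mV", "intracellular_V")
  expect_equal(nSpikes(detectSpikes(flat)), 0)

  ## three synthetic APs at known peak times
  v <- rep(-70, fs)
  peakAt <- c(0.1, 0.25, 0.6)
  for (tp in peakAt) {
    i <- round(tp * fs) + 1
    v[(i - 20):(i + 20)] <- -70 + 100 * exp(-abs(-20:20) / 6)
  }
  sp <- detectSpikes(Trace(v, fs, "mV", "intracellular_V"))
  expect_equal(nSpikes(sp), 3)
  expect_lt(max(abs(spikeTimes(sp) - peakAt)), 1 / fs + 1e-12)

  ## a doublet 1 ms apart collapses to one event under the 2 ms refractory
  v <- rep(-70, fs)
  i <- round(0.5 * fs)
  v[(i - 5):(i + 5)] <- 30
  j <- i + round(0.001 * fs)
  v[(j + 6):(j + 16)] <- 25
  expect_equal(nSpikes(detectSpikes(Trace(v, fs, "mV", "intracellular_V"))), 1)
})

test_that("passive properties are exact on analytic RC responses", {
  ## ranges spanning the reported populations
  for (R in c(50, 200, 600)) {
    for (tauMs in c(5, 30, 60)) {
      ss <- rcSweepSet(R, tauMs / 1000)
      pp <- passiveProperties(ss)
      expect_lt(abs(pp@ri - R), 0.01 * R + 2)
      expect_lt(abs(pp@tauMemb - tauMs), min(1, 0.03 * tauMs))
      expect_equal(pp@vRest, -70, tolerance = 1e-6)
    }
  }
})

test_that("a -25 pA step over 200 MOhm deflects -5 mV at steady state", {
  tr <- rcStepTrace(200, 0.03, -25)
  fs <- samplingRate(tr)
  ss <- mean(samples(tr)[round(2.0 * fs):round(2.49 * fs)])
  expect_equal(ss - (-70), -5, tolerance = 0.01)
})

test_that("spike contamination in a subthreshold sweep is refused", {
  ss <- rcSweepSet(200, 0.03)
  v <- samples(ss@traces[[3]])
  v[30000:30010] <- 20
  ss@traces[[3]] <- Trace(v, samplingRate(ss@traces[[3]]), "mV",
                          "intracellular_V")
  expect_error(passiveProperties(ss), "spikes")
})

test_that("AP features recover a constructed threshold, amplitude and width", {
  tr <- syntheticAP(vThrTrue = -43, peak = 30)
  sp <- detectSpikes(tr)
  expect_equal(nSpikes(sp), 1)
  f <- apFeatures(tr, spikeTimes(sp)[1])
  expect_lt(abs(f@threshold - (-43)), 0.5)
  expect_equal(f@amplitude, f@peak - f@threshold)
  ## amplitude arithmetic: peak ~30, threshold ~-43
  expect_lt(abs(f@amplitude - 73), 1)
  expect_gt(f@halfWidth, 0)

  ## voltage-offset invariance: amplitude and width unchanged, threshold
  ## shifts by the offset
  tr2 <- Trace(samples(tr) + 7, samplingRate(tr), "mV", "intracellular_V")
  f2 <- apFeatures(tr2, spikeTimes(sp)[1])
  expect_equal(f2@threshold - f@threshold, 7, tolerance = 1e-6)
  expect_equal(f2@amplitude, f@amplitude, tolerance = 1e-6)
  expect_equal(f2@halfWidth, f@halfWidth, tolerance = 1e-6)
})

test_that("half-width of a triangular spike matches its geometry", {
  fs <- 100000
  vBase <- -60; peak <- 40
  ## linear flanks: rise 1 ms, fall 2 ms; width at level v is
  ## (1 - frac) * (1 + 2) ms where frac = (v - vBase) / (peak - vBase)
  riseN <- fs / 1000; fallN <- 2 * fs / 1000
  v <- c(rep(vBase, 500),
         seq(vBase, peak, length.out = riseN + 1),
         seq(peak, vBase, length.out = fallN + 1)[-1],
         rep(vBase, 500))
  tr <- Trace(v, fs, "mV", "intracellular_V")
  sp <- detectSpikes(tr)
  f <- apFeatures(tr, spikeTimes(sp)[1], windowMs = 4)
  frac <- (f@threshold + f@amplitude / 2 - vBase) / (peak - vBase)
  expectedMs <- (1 - frac) * 3
  expect_lt(abs(f@halfWidth - expectedMs), 2 * 1000 / fs)
})

test_that("the F-I fit recovers noiseless logarithmic parameters", {
  I <- seq(125, 500, by = 25)
  r <- 150 * log(I / 100)
  fit <- fiFitRates(c(seq(25, 100, by = 25), I), c(rep(0, 4), r))
  expect_lt(abs(fit@gain - 150), 1.5)
  expect_lt(abs(fit@rheobase - 100), 1)
  ## model identity f(rheobase) = 0 and a point evaluation
  expect_equal(fit@gain * log(fit@rheobase / fit@rheobase), 0)
  expect_equal(150 * log(200 / 100), 103.97, tolerance = 0.01)
  expect_equal(fit@maxRate, max(r))
})

test_that("the F-I fit refuses underdetermined curves", {
  expect_error(fiFitRates(c(100, 200, 300), c(0, 10, 20)),
               "at least 4")
})

test_that("injCurr50 is interpolated from the measured curve", {
  I <- c(100, 200, 300, 400, 500)
  r <- c(0, 40, 80, 90, 100)
  fit <- fiFitRates(I, r)
  ## max rate 100 -> half 50, crossed between 200 (40) and 300 (80)
  expect_equal(fit@injCurr50, 200 + (50 - 40) / 40 * 100, tolerance = 1e-9)
})

test_that("the sweep-level F-I path recovers parameters from traces", {
  sim <- simulateCurrentSteps(neuronSimConfig(gain = 150, rheobase = 100,
                                              seed = 2))
  fit <- fiFit(sim$sweeps)
  ## spike counts quantise rates to 0.5 Hz; allow the matching tolerance
  expect_lt(abs(fit@gain - 150) / 150, 0.02)
  expect_lt(abs(fit@rheobase - 100) / 100, 0.02)
})

test_that("F-I fits are unbiased under 5 Hz rate noise", {
  set.seed(99)
  I <- seq(25, 500, by = 25)
  gains <- numeric(100); rheos <- numeric(100)
  for (k in seq_len(100)) {
    r <- ifelse(I > 120, 180 * log(I / 120), 0)
    r <- pmax(0, r + rnorm(length(r), 0, 5) * (r > 0))
    fit <- try(fiFitRates(I, r), silent = TRUE)
    gains[k] <- if (inherits(fit, "try-error")) NA else fit@gain
    rheos[k] <- if (inherits(fit, "try-error")) NA else fit@rheobase
  }
  expect_lt(abs(mean(gains, na.rm = TRUE) - 180) / 180, 0.05)
  expect_lt(abs(mean(rheos, na.rm = TRUE) - 120) / 120, 0.05)
})
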