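## Square-wave evidence with a prescribed component separation, bypassing
## the LFP stage to test the mixture/threshold/refinement logic on its own.
squareEvidence <- function(upMs = 500, downMs = 500, dur = 60, fs = 1000,
                           sep = 8, sd0 = 1, seed = 1) {
  set.seed(seed)
  n <- dur * fs
  period <- (upMs + downMs) / 1000 * fs
  phase <- (seq_len(n) - 1) %% period
  up <- phase < upMs / 1000 * fs
  s <- ifelse(up, sep / 2, -sep / 2) + rnorm(n, sd = sd0)
  ev <- new("StateEvidence", sComb = s, samplingRate = fs, t0 = 0,
            slowPhaseTerm = s * 0, highFreqTerm = s, window = 100)
  list(ev = ev, up = up)
}

test_that("state evidence separates simulated UP and DOWN periods", {
  sim <- simulateInVivo(inVivoSimConfig(duration = 60, juxtaRate = 1000,
                                        seed = 61))
  ev <- stateEvidence(lowpass(sim$lfp, 100))
  states <- sim$truth$states
  fs <- samplingRate(ev)
  lab <- rep(NA, length(ev@sComb))
  for (i in seq_len(nrow(states))) {
    i1 <- floor(states$start[i] * fs) + 1
    i2 <- min(length(lab), ceiling(states$end[i] * fs))
    lab[i1:i2] <- states$label[i]
  }
  expect_gt(mean(ev@sComb[lab == "UP"]) - mean(ev@sComb[lab == "DOWN"]), 2)
})

test_that("state evidence is invariant to scaling the LFP", {
  sim <- simulateInVivo(inVivoSimConfig(duration = 30, juxtaRate = 1000,
                                        seed = 67))
  lfp <- lowpass(sim$lfp, 100)
  ev1 <- stateEvidence(lfp)
  ev2 <- stateEvidence(Trace(10 * samples(lfp), samplingRate(lfp), "uV",
                             "lfp"))
  expect_equal(ev1@sComb, ev2@sComb, tolerance = 1e-9)
})

test_that("white-noise evidence yields no separated mixture", {
  set.seed(71)
  lfp <- Trace(rnorm(60 * 1000), 1000, "uV", "lfp")
  ev <- stateEvidence(lfp)
  fit <- mclust::Mclust(ev@sComb[seq(1, length(ev@sComb), by = 5)], G = 3,
                        modelNames = "V", verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  sg <- sqrt(fit$parameters$variance$sigmasq)
  expect_lt(max(diff(mu)), 2 * max(sg))
})

test_that("segmentation recovers square-wave boundaries and state count", {
  sq <- squareEvidence(sep = 8, seed = 73)
  res <- detectStates(sq$ev)
  seg <- stateIntervals(res$segmentation)
  ups <- seg[seg$label == "UP", ]
  ## 60 s of 0.5/0.5 s alternation starting UP: 60 UP states
  expect_equal(nrow(ups), 60)
  trueStarts <- seq(0, 59.5, by = 1)
  err <- abs(ups$start - trueStarts)
  expect_lt(max(err), 0.010 + 1e-9)
  errEnd <- abs(ups$end - (trueStarts + 0.5))
  expect_lt(max(errEnd), 0.010 + 1e-9)
})

test_that("a 30 ms blip is removed by the duration rule", {
  sq <- squareEvidence(sep = 8, seed = 79)
  s <- sq$ev@sComb
  ## inject a 30 ms UP blip in the middle of a DOWN state
  i0 <- round(0.70 * 1000)
  s[i0:(i0 + 29)] <- 4 + rnorm(30, sd = 0.5)
  sq$ev@sComb <- s
  res <- detectStates(sq$ev)
  seg <- stateIntervals(res$segmentation)
  ups <- seg[seg$label == "UP", ]
  blip <- ups$start > 0.60 & ups$end < 0.90
  expect_false(any(blip))
  durMs <- (ups$end - ups$start) * 1000
  expect_true(all(durMs >= 70 - 1e-6))
})

test_that("same-label runs separated by a sub-50 ms intermediate gap merge", {
  fs <- 1000
  set.seed(83)
  ## periodic pattern with a genuine three-level structure; each period
  ## contains two 200 ms UP runs split by a 40 ms intermediate gap
  block <- c(rep(4, 200), rep(0, 40), rep(4, 200), rep(0, 560),
             rep(-4, 500), rep(0, 500))
  s <- rep(block, 30) + rnorm(30 * length(block), 0, 0.4)
  ev <- new("StateEvidence", sComb = s, samplingRate = fs, t0 = 0,
            slowPhaseTerm = s * 0, highFreqTerm = s, window = 100)
  res <- detectStates(ev)
  seg <- stateIntervals(res$segmentation)
  ups <- seg[seg$label == "UP", ]
  ## the 40 ms gaps are filled: one 440 ms UP interval per period, not two
  expect_equal(nrow(ups), 30)
  durMs <- (ups$end - ups$start) * 1000
  expect_true(all(durMs > 400))
})

test_that("labels are invariant to affine transforms of the LFP", {
  sim <- simulateInVivo(inVivoSimConfig(duration = 40, juxtaRate = 1000,
                                        seed = 89))
  lfp <- lowpass(sim$lfp, 100)
  r1 <- detectStates(stateEvidence(lfp))
  lfp2 <- Trace(3.7 * samples(lfp) + 120, samplingRate(lfp), "uV", "lfp")
  r2 <- detectStates(stateEvidence(lfp2))
  ## the evidence is analytically affine-invariant; allow isolated sample
  ## flips from floating-point rounding near the thresholds
  lab <- function(res) {
    iv <- stateIntervals(res$segmentation)
    out <- character(40 * 1000)
    for (i in seq_len(nrow(iv)))
      out[(floor(iv$start[i] * 1000) + 1):ceiling(iv$end[i] * 1000)] <-
        iv$label[i]
    out
  }
  expect_gt(mean(lab(r1) == lab(r2)), 0.995)
})

test_that("degenerate mixtures are refused with a diagnostic", {
  ## two components collapsed onto each other (means 0.01 apart, sd 1)
  expect_error(ephyskit:::.makeGMMFit(c(0, 0.01, 5), c(1, 1, 0.5),
                                      c(0.4, 0.4, 0.2)),
               "degenerate")
  ## well-separated components pass and thresholds sit 3 sd inside
  g <- ephyskit:::.makeGMMFit(c(5, -4, 0), c(0.5, 0.5, 0.5),
                              c(0.3, 0.4, 0.3))
  expect_equal(g@means, c(-4, 0, 5))
  expect_equal(g@thUp, 5 - 1.5)
  expect_equal(g@thDown, -4 + 1.5)
})

test_that("state statistics count, time and rate per label", {
  iv <- data.frame(start = seq(0, 59, by = 2),
                   end = seq(1, 60, by = 2), label = "UP")
  iv <- rbind(iv, data.frame(start = seq(1, 59, by = 2),
                             end = seq(2, 60, by = 2), label = "DOWN"))
  iv <- iv[order(iv$start), ]
  seg <- new("StateSegmentation", intervals = iv, minInterval = 50,
             minDuration = 70, recordDuration = 60)
  ## all spikes inside UP intervals (the even seconds), overall 1 Hz
  spikes <- SpikeTrain(sort(c(seq(0.25, 58.25, by = 2),
                              seq(0.75, 58.75, by = 2))), 60)
  ss <- stateStats(seg, spikes)
  expect_equal(ss$frequencyPerMin[ss$label == "UP"], 30)
  expect_equal(ss$meanDurationMs[ss$label == "UP"], 1000)
  expect_equal(ss$spikeRateHz[ss$label == "UP"], 2)
  expect_equal(ss$spikeRateHz[ss$label == "DOWN"], 0)
  expect_false(ss$present[ss$label == "INTERMEDIATE"])
  expect_true(is.na(ss$spikeRateHz[ss$label == "INTERMEDIATE"]))
})

test_that("the full detect-then-stats chain recovers state-conditional rates", {
  sim <- simulateInVivo(inVivoSimConfig(duration = 300, juxtaRate = 1000,
                                        spikeRateUp = 4, spikeRateDown = 0.2,
                                        seed = 101))
  lfp <- lowpass(sim$lfp, 100)
  res <- detectStates(stateEvidence(lfp))
  ss <- stateStats(res$segmentation, sim$spikes)
  expect_lt(abs(ss$spikeRateHz[ss$label == "UP"] - 4) / 4, 0.15)
  expect_lt(abs(ss$spikeRateHz[ss$label == "DOWN"] - 0.2) / 0.2, 0.5)
})
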