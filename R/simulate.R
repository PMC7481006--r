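#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## von Mises sampling (Best & Fisher rejection sampler). kappa = 0 reduces to
## the uniform distribution on (-pi, pi].

#' Draw von Mises distributed angles
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives uniform angles.
#' @return Angles in (-pi, pi].
#' @export
rVonMises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(.wrapAngle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, as.integer(1.5 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(f))[ok])
  }
  .wrapAngle(out[seq_len(n)] + mu)
}

## ---------------------------------------------------------------------------
## In vivo simulator

#' Configuration for the in vivo simulator
#'
#' Defaults emulate urethane-anesthesia cortical dynamics: UP/DOWN
#' alternation with gamma-distributed state durations (shape 4, mean 500 ms
#' each, floored at 80 ms so sub-minimum states do not dominate), a slow
#' (< 4 Hz) LFP rhythm following the state alternation, 20-100 Hz activity
#' enriched in UP states, state-dependent Poisson spiking, and optional von
#' Mises phase coupling of UP-state spikes to a chosen LFP band. The
#' juxtacellular channel carries a biphasic spike waveform (1.5 ms wide,
#' 2-4 mV) on 0.2 mV noise, so the 1.5 mV detection threshold is
#' meaningfully exercised.
#'
#' @param duration recording duration (s).
#' @param lfpRate LFP sampling rate (Hz); 1 kHz is the analysis rate.
#' @param juxtaRate juxtacellular sampling rate (Hz); recordings are
#'   acquired at 20 kHz.
#' @param upDurationMean,downDurationMean mean state durations (ms).
#' @param durationShape gamma shape of the state-duration distribution.
#' @param durationFloorMs truncation floor of state durations (ms).
#' @param slowCutoff low-pass cutoff (Hz) shaping the slow rhythm from the
#'   state sequence (< 4 Hz).
#' @param slowAmp slow-rhythm amplitude (uV).
#' @param hfBand high-frequency band (Hz) enriched during UP states.
#' @param hfAmpUp RMS amplitude (uV) of the high-frequency component in UP.
#' @param hfPowerRatioUpDown UP/DOWN power ratio of the hf component.
#' @param spikeRateUp,spikeRateDown state-conditional spike rates (Hz).
#' @param couplingBand LFP band (Hz) that UP-state spikes phase-lock to.
#' @param kappa von Mises concentration of the coupling (0 = none).
#' @param preferredPhase preferred phase (radians).
#' @param noiseSd white LFP noise SD (uV).
#' @param spikeAmp juxtacellular spike amplitude (mV).
#' @param juxtaNoiseSd juxtacellular noise SD (mV).
#' @param seed integer seed; the simulation is bitwise reproducible.
#' @return A config list for [simulateInVivo()].
#' @export
inVivoSimConfig <- function(duration = 600, lfpRate = 1000,
                            juxtaRate = 20000,
                            upDurationMean = 500, downDurationMean = 500,
                            durationShape = 4, durationFloorMs = 80,
                            slowCutoff = 2, slowAmp = 100,
                            hfBand = c(20, 100), hfAmpUp = 30,
                            hfPowerRatioUpDown = 10,
                            spikeRateUp = 4, spikeRateDown = 0.2,
                            couplingBand = c(20, 40), kappa = 0,
                            preferredPhase = 0, noiseSd = 10,
                            spikeAmp = 2.5, juxtaNoiseSd = 0.2, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$couplingBand[2] > cfg$lfpRate / 2)
    stop("coupling band exceeds the LFP Nyquist frequency", call. = FALSE)
  if (cfg$hfBand[2] > cfg$lfpRate / 2)
    stop("hf band exceeds the LFP Nyquist frequency", call. = FALSE)
  if (any(c(cfg$spikeRateUp, cfg$spikeRateDown) < 0) || cfg$kappa < 0)
    stop("rates and kappa must be non-negative", call. = FALSE)
  if (cfg$durationFloorMs < 70)
    stop("state-duration floor below the 70 ms analysis minimum",
         call. = FALSE)
  cfg
}

.biphasicTemplate <- function(rate, widthMs = 1.5) {
  ## positive lobe followed by a shallower negative lobe; peak amplitude 1
  n <- max(5L, as.integer(round(widthMs / 1000 * rate)))
  if (n %% 2L == 0L) n <- n + 1L
  t <- seq(-1, 1, length.out = n)
  w <- exp(-(t / 0.35)^2) - 0.45 * exp(-((t - 0.55) / 0.45)^2)
  w / max(w)
}

.drawStates <- function(cfg) {
  meanS <- c(UP = cfg$upDurationMean, DOWN = cfg$downDurationMean) / 1000
  floorS <- cfg$durationFloorMs / 1000
  labs <- character(0); durs <- numeric(0)
  state <- if (stats::runif(1) < 0.5) "UP" else "DOWN"
  total <- 0
  while (total < cfg$duration) {
    d <- max(stats::rgamma(1, shape = cfg$durationShape,
                           scale = meanS[[state]] / cfg$durationShape),
             floorS)
    d <- min(d, cfg$duration - total)
    labs <- c(labs, state); durs <- c(durs, d)
    total <- total + d
    state <- if (state == "UP") "DOWN" else "UP"
  }
  ends <- cumsum(durs)
  data.frame(start = ends - durs, end = ends, label = labs,
             stringsAsFactors = FALSE)
}

#' Simulate a dual-channel in vivo recording
#'
#' Generates a two-state (UP/DOWN) LFP plus a juxtacellular channel with
#' known ground truth: a semi-Markov UP/DOWN alternation; an LFP that is the
#' sum of a slow rhythm (the low-passed state sequence), state-gated
#' band-limited high-frequency noise, and white noise; state-conditional
#' Poisson spiking, with UP-state spikes phase-coupled (von Mises, rejection
#' sampled against the actual coupling-band phase of the generated LFP) when
#' `kappa > 0`; and a juxtacellular trace carrying a biphasic spike waveform
#' at each spike time.
#'
#' @param cfg an [inVivoSimConfig()] list.
#' @return A list with `lfp` ([Trace-class], uV), `juxta` ([Trace-class],
#'   mV), `spikes` ([SpikeTrain-class]) and `truth` (state intervals, spike
#'   times, spike phases, and the config).
#' @export
simulateInVivo <- function(cfg = inVivoSimConfig()) {
  set.seed(cfg$seed)
  fs <- cfg$lfpRate
  n <- as.integer(round(cfg$duration * fs))
  states <- .drawStates(cfg)
  upMask <- logical(n)
  for (i in which(states$label == "UP")) {
    i1 <- as.integer(floor(states$start[i] * fs)) + 1L
    i2 <- min(n, as.integer(ceiling(states$end[i] * fs)))
    upMask[i1:i2] <- TRUE
  }
  sq <- ifelse(upMask, 1, -1)
  slow <- .filtfilt(
    signal::butter(4, cfg$slowCutoff / (fs / 2), type = "low")$b,
    signal::butter(4, cfg$slowCutoff / (fs / 2), type = "low")$a, sq)
  slow <- cfg$slowAmp * slow
  hfRaw <- .filtfilt(
    signal::butter(4, cfg$hfBand / (fs / 2), type = "pass")$b,
    signal::butter(4, cfg$hfBand / (fs / 2), type = "pass")$a,
    stats::rnorm(n))
  hfRaw <- hfRaw / stats::sd(hfRaw)
  gate <- ifelse(upMask, cfg$hfAmpUp,
                 cfg$hfAmpUp / sqrt(cfg$hfPowerRatioUpDown))
  gate <- .movavg(gate, as.integer(round(0.01 * fs)))
  lfpSamples <- slow + gate * hfRaw + stats::rnorm(n, sd = cfg$noiseSd)
  lfp <- Trace(lfpSamples, fs, "uV", "lfp")
  ## spikes: per-interval Poisson counts; phase coupling during UP states
  couplingPhase <- NULL
  if (cfg$kappa > 0)
    couplingPhase <- hilbertPhase(lfp, cfg$couplingBand)@phases
  spikeTimesAll <- numeric(0)
  for (i in seq_len(nrow(states))) {
    lab <- states$label[i]
    rate <- if (lab == "UP") cfg$spikeRateUp else cfg$spikeRateDown
    len <- states$end[i] - states$start[i]
    k <- stats::rpois(1, rate * len)
    if (!k) next
    if (lab == "UP" && cfg$kappa > 0) {
      got <- numeric(0)
      while (length(got) < k) {
        cand <- stats::runif(2 * (k - length(got)) + 8,
                             states$start[i], states$end[i])
        idx <- pmin(n, pmax(1L, .sampleIndex(cand, fs)))
        p <- exp(cfg$kappa * (cos(couplingPhase[idx] - cfg$preferredPhase) - 1))
        got <- c(got, cand[stats::runif(length(cand)) < p])
      }
      spikeTimesAll <- c(spikeTimesAll, got[seq_len(k)])
    } else {
      spikeTimesAll <- c(spikeTimesAll, stats::runif(k, states$start[i],
                                                     states$end[i]))
    }
  }
  spikeTimesAll <- sort(spikeTimesAll)
  ## enforce a 2 ms minimum separation so the juxta waveforms do not overlap
  if (length(spikeTimesAll) > 1) {
    keep <- c(TRUE, diff(spikeTimesAll) > 0.002)
    spikeTimesAll <- spikeTimesAll[keep]
  }
  spikes <- SpikeTrain(spikeTimesAll, cfg$duration)
  truthPhases <- if (!is.null(couplingPhase) && length(spikeTimesAll))
    couplingPhase[pmin(n, pmax(1L, .sampleIndex(spikeTimesAll, fs)))]
  else rep(NA_real_, length(spikeTimesAll))
  ## juxtacellular channel
  nj <- as.integer(round(cfg$duration * cfg$juxtaRate))
  jux <- stats::rnorm(nj, sd = cfg$juxtaNoiseSd)
  tmpl <- cfg$spikeAmp * .biphasicTemplate(cfg$juxtaRate)
  half <- (length(tmpl) - 1L) %/% 2L
  for (tSp in spikeTimesAll) {
    c0 <- .sampleIndex(tSp, cfg$juxtaRate)
    i1 <- c0 - half; i2 <- c0 + half
    if (i1 < 1L || i2 > nj) next
    jux[i1:i2] <- jux[i1:i2] + tmpl
  }
  juxta <- Trace(jux, cfg$juxtaRate, "mV", "juxtacellular_V")
  list(lfp = lfp, juxta = juxta, spikes = spikes,
       truth = list(states = states, spikeTimes = spikeTimesAll,
                    spikePhases = truthPhases, config = cfg))
}

## ---------------------------------------------------------------------------
## Current-step simulator

#' Configuration for the current-step simulator
#'
#' Two generating models: `"rate"` draws spike counts from the logarithmic
#' rate model `f(I) = gain * ln(I / rheobase)` (optionally with Gaussian
#' rate noise) and places spikes quasi-regularly with uniform jitter;
#' `"lif"` integrates a leaky integrate-and-fire neuron (exact RC passive
#' response, closed-form rheobase `(vThr - vRest) / R`). Subthreshold
#' -25/0/+25 pA sweeps are always included.
#'
#' @param model `"rate"` or `"lif"`.
#' @param currents injected currents (pA) for the suprathreshold protocol.
#' @param gain,rheobase rate-model parameters (Hz, pA).
#' @param rateNoiseSd rate-model rate noise SD (Hz; 0 = noiseless).
#' @param R,tauMs,vRest,vThr,vReset,refractoryMs LIF parameters
#'   (MOhm, ms, mV, mV, mV, ms).
#' @param stepOnset,stepDuration step timing (s); steps last 2 s.
#' @param samplingRate sweep sampling rate (Hz).
#' @param seed integer seed.
#' @return A config list for [simulateCurrentSteps()].
#' @export
neuronSimConfig <- function(model = c("rate", "lif"),
                            currents = seq(25, 500, by = 25),
                            gain = 150, rheobase = 100, rateNoiseSd = 0,
                            R = 200, tauMs = 30, vRest = -70, vThr = -45,
                            vReset = -60, refractoryMs = 3,
                            stepOnset = 0.5, stepDuration = 2,
                            samplingRate = 20000, seed = 1) {
  model <- match.arg(model)
  cfg <- as.list(environment())
  stopifnot(gain > 0, rheobase > 0, R > 0, tauMs > 0, stepDuration > 0)
  cfg
}

.apWaveform <- function(rate, vBase, peak = 30) {
  ## stylized action potential: fast exponential rise over ~1 ms to the
  ## peak, 1.5 ms repolarisation; dV/dt crosses 10 mV/ms early in the rise
  tUp <- seq(0, 1, length.out = max(3L, as.integer(round(rate / 1000))))
  rise <- vBase + (peak - vBase) * (exp(3 * tUp) - 1) / (exp(3) - 1)
  tDn <- seq(0, 1.5, length.out = max(4L, as.integer(round(1.5 * rate / 1000))))
  fall <- vBase + (peak - vBase) * exp(-tDn / 0.35)
  c(rise, fall[-1])
}

#' Simulate a current-step excitability experiment
#'
#' @param cfg a [neuronSimConfig()] list.
#' @return A list with `sweeps` ([SweepSet-class]) and `truth` (generating
#'   parameters, including the analytic LIF rheobase when applicable).
#' @export
simulateCurrentSteps <- function(cfg = neuronSimConfig()) {
  set.seed(cfg$seed)
  fs <- cfg$samplingRate
  sweepDur <- cfg$stepOnset + cfg$stepDuration + 0.5
  nSamp <- as.integer(round(sweepDur * fs))
  tt <- (seq_len(nSamp) - 1) / fs
  inStep <- tt >= cfg$stepOnset & tt < cfg$stepOnset + cfg$stepDuration
  tauS <- cfg$tauMs / 1000
  currents <- sort(unique(c(-25, 0, 25, cfg$currents)))
  rcResponse <- function(I) {
    ## passive RC response to the step, mV (R in MOhm, I in pA: R*I in mV
    ## after the 1e-3 scale factor)
    dv <- cfg$R * I * 1e-3
    v <- rep(cfg$vRest, nSamp)
    tin <- tt[inStep] - cfg$stepOnset
    v[inStep] <- cfg$vRest + dv * (1 - exp(-tin / tauS))
    post <- tt >= cfg$stepOnset + cfg$stepDuration
    vEnd <- cfg$vRest + dv * (1 - exp(-cfg$stepDuration / tauS))
    v[post] <- cfg$vRest + (vEnd - cfg$vRest) *
      exp(-(tt[post] - (cfg$stepOnset + cfg$stepDuration)) / tauS)
    v
  }
  addSpikes <- function(v, spikeT) {
    for (tSp in spikeT) {
      wf <- .apWaveform(fs, vBase = v[.sampleIndex(tSp, fs)])
      i1 <- .sampleIndex(tSp, fs)
      i2 <- min(nSamp, i1 + length(wf) - 1L)
      v[i1:i2] <- wf[seq_len(i2 - i1 + 1L)]
    }
    v
  }
  truthRheo <- if (cfg$model == "lif")
    (cfg$vThr - cfg$vRest) / cfg$R * 1000 else cfg$rheobase
  traces <- lapply(currents, function(I) {
    if (cfg$model == "rate") {
      v <- rcResponse(min(I, 25))   # clamp passive drive for display only
      if (I > 0) {
        f <- if (I > cfg$rheobase) cfg$gain * log(I / cfg$rheobase) else 0
        if (cfg$rateNoiseSd > 0) f <- max(0, f + stats::rnorm(1, 0, cfg$rateNoiseSd))
        k <- round(f * cfg$stepDuration)
        if (k > 0) {
          iso <- cfg$stepDuration / k
          spikeT <- cfg$stepOnset + (seq_len(k) - 0.75) * iso +
            stats::runif(k, -0.2 * iso, 0.2 * iso)
          spikeT <- spikeT[spikeT < cfg$stepOnset + cfg$stepDuration - 0.004]
          v <- addSpikes(v, spikeT)
        }
      }
      Trace(v, fs, "mV", "intracellular_V")
    } else {
      v <- numeric(nSamp)
      v[1] <- cfg$vRest
      dt <- 1 / fs
      refSamp <- as.integer(round(cfg$refractoryMs / 1000 * fs))
      spikeT <- numeric(0)
      hold <- 0L
      dvIn <- cfg$R * I * 1e-3
      for (i in 2:nSamp) {
        if (hold > 0L) {
          v[i] <- cfg$vReset
          hold <- hold - 1L
          next
        }
        drive <- if (inStep[i]) dvIn else 0
        v[i] <- v[i - 1] + dt / tauS * (cfg$vRest - v[i - 1] + drive)
        if (v[i] >= cfg$vThr && inStep[i]) {
          spikeT <- c(spikeT, tt[i])
          hold <- refSamp
          v[i] <- cfg$vReset
        }
      }
      Trace(addSpikes(v, spikeT), fs, "mV", "intracellular_V")
    }
  })
  list(sweeps = SweepSet(currents, traces, cfg$stepOnset, cfg$stepDuration),
       truth = list(model = cfg$model, gain = cfg$gain,
                    rheobase = truthRheo, R = cfg$R, tauMs = cfg$tauMs,
                    vRest = cfg$vRest, config = cfg))
}

## ---------------------------------------------------------------------------
## Quantal synaptic-train simulator

#' Configuration for the quantal synaptic-train simulator
#'
#' Binomial quantal release at each of 5 pulses (50 Hz): `Binom(nSites,
#' pEff)` quanta per pulse, each contributing a difference-of-exponentials
#' postsynaptic current of peak `q` pA. With depression, the release
#' probability follows the resource recursion `x[1] = 1`,
#' `x[n+1] = 1 - (1 - x[n] (1 - U)) exp(-ISI / tauRec)` with
#' `pEff[n] = pRelease * x[n]`; with facilitation, `pEff[n] = min(1,
#' pRelease * f[n])` with `f[1] = 1`, `f[n+1] = 1 + (f[n] + F - 1)
#' exp(-ISI / tauFacil)`.
#'
#' @param nSites number of release sites (>= 1).
#' @param pRelease baseline release probability, in [0, 1].
#' @param q quantal peak amplitude (pA).
#' @param pscRiseMs,pscDecayMs PSC kinetics (ms).
#' @param plasticity `NULL`, or `list(type = "depression", U, tauRecMs)`, or
#'   `list(type = "facilitation", F, tauFacilMs)`.
#' @param nSweeps number of sweeps.
#' @param noiseSd Gaussian current noise SD (pA).
#' @param polarity `"inward"` or `"outward"`.
#' @param samplingRate Hz.
#' @param stimStart first stimulus time (s).
#' @param isi inter-stimulus interval (s); 20 ms = 50 Hz.
#' @param nPulses pulses per train.
#' @param sweepDuration sweep length (s).
#' @param seed integer seed.
#' @return A config list for [simulateSynapticTrains()].
#' @export
synapseSimConfig <- function(nSites = 5, pRelease = 0.8, q = 20,
                             pscRiseMs = 0.8, pscDecayMs = 15,
                             plasticity = NULL, nSweeps = 50, noiseSd = 2,
                             polarity = c("inward", "outward"),
                             samplingRate = 10000, stimStart = 0.1,
                             isi = 0.02, nPulses = 5, sweepDuration = 0.5,
                             seed = 1) {
  polarity <- match.arg(polarity)
  cfg <- as.list(environment())
  stopifnot(nSites >= 1, pRelease >= 0, pRelease <= 1)
  cfg
}

## Per-pulse effective release probabilities under the configured
## short-term plasticity; also the analytic mean-amplitude ratios.
.plasticityProfile <- function(cfg) {
  p <- rep(cfg$pRelease, cfg$nPulses)
  if (!is.null(cfg$plasticity)) {
    pl <- cfg$plasticity
    if (pl$type == "depression") {
      x <- numeric(cfg$nPulses); x[1] <- 1
      for (i in seq_len(cfg$nPulses - 1))
        x[i + 1] <- 1 - (1 - x[i] * (1 - pl$U)) * exp(-cfg$isi / (pl$tauRecMs / 1000))
      p <- cfg$pRelease * x
    } else if (pl$type == "facilitation") {
      f <- numeric(cfg$nPulses); f[1] <- 1
      for (i in seq_len(cfg$nPulses - 1))
        f[i + 1] <- 1 + (f[i] + pl$F - 1) * exp(-cfg$isi / (pl$tauFacilMs / 1000))
      p <- pmin(1, cfg$pRelease * f)
    } else stop("unknown plasticity type", call. = FALSE)
  }
  p
}

.pscKernel <- function(cfg) {
  tauR <- cfg$pscRiseMs / 1000; tauD <- cfg$pscDecayMs / 1000
  tk <- seq(0, tauD * 8, by = 1 / cfg$samplingRate)
  k <- exp(-tk / tauD) - exp(-tk / tauR)
  k / max(k)
}

#' Simulate unitary synaptic trains with quantal release
#'
#' @param cfg a [synapseSimConfig()] list.
#' @return A list with `recording` ([PairedTrainRecording-class]) and
#'   `truth` (per-sweep quantal outcomes, effective release probabilities,
#'   analytic mean amplitudes and amplitude ratios).
#' @export
simulateSynapticTrains <- function(cfg = synapseSimConfig()) {
  set.seed(cfg$seed)
  fs <- cfg$samplingRate
  n <- as.integer(round(cfg$sweepDuration * fs))
  stim <- cfg$stimStart + (seq_len(cfg$nPulses) - 1) * cfg$isi
  pEff <- .plasticityProfile(cfg)
  kern <- .pscKernel(cfg)
  s <- if (cfg$polarity == "inward") -1 else 1
  quanta <- matrix(0L, cfg$nSweeps, cfg$nPulses)
  sweeps <- vector("list", cfg$nSweeps)
  for (sw in seq_len(cfg$nSweeps)) {
    x <- stats::rnorm(n, sd = cfg$noiseSd)
    for (pu in seq_len(cfg$nPulses)) {
      k <- stats::rbinom(1, cfg$nSites, pEff[pu])
      quanta[sw, pu] <- k
      if (k > 0) {
        i1 <- .sampleIndex(stim[pu], fs)
        i2 <- min(n, i1 + length(kern) - 1L)
        x[i1:i2] <- x[i1:i2] + s * k * cfg$q * kern[seq_len(i2 - i1 + 1L)]
      }
    }
    sweeps[[sw]] <- Trace(x, fs, "pA", "intracellular_I")
  }
  rec <- PairedTrainRecording(sweeps, stim,
                              baselineWindow = c(0, cfg$stimStart - 0.005),
                              polarity = cfg$polarity)
  list(recording = rec,
       truth = list(quanta = quanta, pEff = pEff,
                    meanAmp = cfg$nSites * pEff * cfg$q,
                    ampRatios = pEff / pEff[1],
                    failureP = (1 - pEff)^cfg$nSites, config = cfg))
}
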