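## Independent oracles used across tests.

## O(N^2) pairwise phase consistency: the defining double sum over all
## pairs, cos(ti)cos(tj) + sin(ti)sin(tj), computed literally (vectorized
## over the upper triangle), independent of the resultant-length identity.
ppcBruteForce <- function(phases) {
  n <- length(phases)
  cc <- outer(cos(phases), cos(phases)) + outer(sin(phases), sin(phases))
  2 * sum(cc[upper.tri(cc)]) / (n * (n - 1))
}

## Analytic RC step response: V(t) = Vrest + I*R*(1 - exp(-t/tau)),
## R in MOhm, I in pA (product in mV after 1e-3), tau in s.
rcStepTrace <- function(R, tauS, I, vRest = -70, fs = 20000,
                        onset = 0.5, stepDur = 2, total = 3) {
  tt <- (seq_len(total * fs) - 1) / fs
  v <- rep(vRest, length(tt))
  dv <- R * I * 1e-3
  inStep <- tt >= onset & tt < onset + stepDur
  v[inStep] <- vRest + dv * (1 - exp(-(tt[inStep] - onset) / tauS))
  post <- tt >= onset + stepDur
  vEnd <- vRest + dv * (1 - exp(-stepDur / tauS))
  v[post] <- vRest + (vEnd - vRest) * exp(-(tt[post] - onset - stepDur) / tauS)
  Trace(v, fs, "mV", "intracellular_V")
}

rcSweepSet <- function(R, tauS, currents = c(-25, 0, 25), vRest = -70,
                       fs = 20000) {
  SweepSet(currents,
           lapply(currents, function(I) rcStepTrace(R, tauS, I, vRest, fs)),
           stepOnset = 0.5, stepDuration = 2)
}

## Tsodyks-Markram-style resource recursion for a depressing train.
depressionRatios <- function(U, tauRecS, isi = 0.02, nPulses = 5) {
  x <- numeric(nPulses); x[1] <- 1
  for (i in seq_len(nPulses - 1))
    x[i + 1] <- 1 - (1 - x[i] * (1 - U)) * exp(-isi / tauRecS)
  x / x[1]
}

## Expected PPC for von Mises phases: squared population resultant length.
vonMisesPPC <- function(kappa) (besselI(kappa, 1) / besselI(kappa, 0))^2

## Synthetic action potential with a prescribed voltage course, built by
## integrating its own dV/dt profile so that the 10 mV/ms crossing voltage
## is known by construction.
syntheticAP <- function(fs = 50000, vBase = -70, vThrTrue = -43,
                        peak = 30) {
  dt <- 1 / fs
  ## ramp dV/dt linearly from 0 to 10 mV/ms while V rises vBase -> vThrTrue,
  ## then jump dV/dt to 400 mV/ms until peak, then decay back
  v <- vBase
  while (v[length(v)] < vThrTrue) {
    frac <- (v[length(v)] - vBase) / (vThrTrue - vBase)
    dvdt <- 0.2 + 9.3 * frac          # stays below the 10 mV/ms criterion
    v <- c(v, v[length(v)] + dvdt * dt * 1000)
  }
  while (v[length(v)] < peak)
    v <- c(v, min(peak, v[length(v)] + 400 * dt * 1000))
  tail <- v[length(v)]
  while (tail > vBase + 0.5) {
    tail <- tail - 250 * dt * 1000
    v <- c(v, max(tail, vBase))
  }
  pad <- rep(vBase, as.integer(0.01 * fs))
  Trace(c(pad, v, pad), fs, "mV", "intracellular_V")
}
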