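#' @include AllClasses.R
NULL

#' Threshold-based spike detection in current-clamp traces
#'
#' One event per upward crossing of the voltage threshold (0 mV by default);
#' the event time is the time of the peak of the suprathreshold excursion.
#' Crossings whose peak falls within the refractory window after the
#' previous accepted spike are ignored. An empty train is a valid result.
#'
#' @param trace a voltage [Trace-class] (mV).
#' @param threshold detection threshold in mV.
#' @param refractory refractory period in ms.
#' @return A [SpikeTrain-class]; times are relative to the trace start.
#' @export
detectSpikes <- function(trace, threshold = 0, refractory = 2) {
  stopifnot(is(trace, "Trace"))
  x <- trace@samples
  fs <- trace@samplingRate
  above <- x > threshold
  if (!any(above))
    return(SpikeTrain(numeric(0), duration(trace)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runStart <- starts[r$values]
  runEnd <- ends[r$values]
  peaks <- vapply(seq_along(runStart), function(i) {
    seg <- runStart[i]:runEnd[i]
    seg[which.max(x[seg])]
  }, integer(1))
  refSamp <- refractory * fs / 1000
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last > refSamp) {
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  SpikeTrain((peaks[keep] - 1) / fs, duration(trace))
}

.steadyWindowS <- 0.5   # last 500 ms of the 2 s step define the steady state

.sweepAt <- function(sweeps, current) {
  i <- which(abs(sweeps@currents - current) < 1e-9)
  if (length(i) != 1)
    stop(sprintf("sweep at %g pA is required but absent", current),
         call. = FALSE)
  sweeps@traces[[i]]
}

.windowMean <- function(trace, from, to) {
  fs <- trace@samplingRate
  i1 <- max(1L, as.integer(floor(from * fs)) + 1L)
  i2 <- min(length(trace@samples), as.integer(ceiling(to * fs)))
  mean(trace@samples[i1:i2])
}

#' Passive membrane properties from subthreshold steps
#'
#' Resting potential is the pre-step mean of the 0 pA sweep; input
#' resistance is the least-squares slope of the steady-state voltage
#' deflection against injected current over the -25, 0 and +25 pA sweeps
#' (steady state = last 500 ms of the step); the membrane time constant is a
#' single-exponential fit of the voltage relaxation after the -25 pA step
#' onset (starting 2 ms in, to skip pipette artifacts). A spike detected in
#' any of the three sweeps aborts with a contamination error.
#'
#' @param sweeps a [SweepSet-class] containing -25, 0 and +25 pA sweeps.
#' @return A [PassiveProperties-class] (mV, MOhm, ms).
#' @export
passiveProperties <- function(sweeps) {
  stopifnot(is(sweeps, "SweepSet"))
  use <- c(-25, 0, 25)
  trs <- lapply(use, function(cc) .sweepAt(sweeps, cc))
  for (i in seq_along(use))
    if (nSpikes(detectSpikes(trs[[i]])) > 0)
      stop(sprintf("subthreshold sweep at %g pA contains spikes", use[i]),
           call. = FALSE)
  onset <- sweeps@stepOnset
  stepEnd <- onset + sweeps@stepDuration
  vRest <- .windowMean(trs[[which(use == 0)]], 0, onset)
  vss <- vapply(trs, .windowMean, numeric(1),
                from = stepEnd - .steadyWindowS, to = stepEnd)
  vpre <- vapply(trs, .windowMean, numeric(1), from = 0, to = onset)
  dV <- vss - vpre
  ## mV / pA = GOhm; report MOhm
  ri <- unname(stats::coef(stats::lm(dV ~ use))[2]) * 1000
  ## tau from the -25 pA sweep
  tr <- trs[[which(use == -25)]]
  fs <- tr@samplingRate
  i0 <- as.integer(round((onset + 0.002) * fs)) + 1L
  i1 <- as.integer(round(stepEnd * fs))
  y <- tr@samples[i0:i1]
  tt <- (seq_along(y) - 1) / fs
  v0 <- mean(y[tt > max(tt) - .steadyWindowS])
  A <- y[1] - v0
  below <- which(abs(y - v0) < abs(A) / exp(1))
  tau0 <- if (length(below)) max(tt[below[1]], 2 / fs) else max(tt) / 5
  fit <- minpack.lm::nlsLM(y ~ v + a * exp(-tt / tau),
                           start = list(v = v0, a = A, tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  tauMemb <- unname(stats::coef(fit)["tau"]) * 1000
  new("PassiveProperties", vRest = vRest, ri = ri, tauMemb = tauMemb)
}

#' Action-potential waveform features
#'
#' Within +/- `windowMs` around a detected spike: threshold is the membrane
#' potential at the first upward crossing of the dV/dt criterion (10 mV/ms)
#' before the peak, amplitude is peak minus threshold, and half-width is the
#' time between the rising and falling crossings of threshold + amplitude/2
#' (both crossings linearly interpolated).
#'
#' @param trace the voltage [Trace-class] (mV).
#' @param spikeTime spike peak time (s), e.g. from [detectSpikes()].
#' @param dvdtCriterion threshold criterion in mV/ms.
#' @param windowMs half-window around the spike (ms).
#' @return An [APFeatures-class].
#' @export
apFeatures <- function(trace, spikeTime, dvdtCriterion = 10, windowMs = 5) {
  stopifnot(is(trace, "Trace"))
  fs <- trace@samplingRate
  half <- as.integer(round(windowMs / 1000 * fs))
  center <- .sampleIndex(spikeTime, fs, trace@t0)
  i1 <- center - half; i2 <- center + half
  if (i1 < 1 || i2 > length(trace@samples))
    stop("spike window extends beyond the trace", call. = FALSE)
  v <- trace@samples[i1:i2]
  pk <- which.max(v)
  vPeak <- v[pk]
  dvdt <- c(diff(v) * fs / 1000, NA)            # mV/ms, forward difference
  pre <- seq_len(pk - 1L)
  cross <- which(dvdt[pre] >= dvdtCriterion &
                 c(-Inf, dvdt[pre[-length(pre)]]) < dvdtCriterion)
  if (!length(cross))
    stop("no dV/dt threshold crossing found before the spike peak",
         call. = FALSE)
  i <- cross[1]
  if (i > 1) {
    frac <- (dvdtCriterion - dvdt[i - 1]) / (dvdt[i] - dvdt[i - 1])
    thr <- v[i - 1] + (v[i] - v[i - 1]) * frac
  } else thr <- v[i]
  amp <- vPeak - thr
  level <- thr + amp / 2
  dt <- 1 / fs
  tUp <- .firstCrossingUp(v[1:pk], level, dt)
  post <- v[pk:length(v)]
  tDown <- .firstCrossingDown(post, level, dt)
  if (is.na(tUp) || is.na(tDown))
    stop("half-width level not crossed on both flanks", call. = FALSE)
  halfWidth <- ((pk - 1) * dt + tDown - tUp) * 1000
  new("APFeatures", threshold = thr, amplitude = amp, halfWidth = halfWidth,
      peak = vPeak)
}

#' Logarithmic F-I fit on measured rates
#'
#' Nonlinear least-squares fit of `rate = gain * ln(I / rheobase)` to the
#' suprathreshold (rate > 0) points of a measured F-I curve, with both
#' parameters constrained positive. Initialisation: rheobase from the
#' largest zero-rate current plus half a step (or half the smallest
#' suprathreshold current), gain from the slope of the first two
#' suprathreshold points in log-current. `injCurr50` is read off the
#' measured curve by linear interpolation (the smallest current at which the
#' interpolated rate reaches half the maximal rate), not off the fit.
#'
#' @param currents injected currents (pA).
#' @param rates measured spiking rates (Hz), parallel to `currents`.
#' @return A [FICurveFit-class].
#' @seealso [fiFit()] for the sweep-level interface.
#' @export
fiFitRates <- function(currents, rates) {
  stopifnot(length(currents) == length(rates))
  ord <- order(currents)
  currents <- currents[ord]; rates <- rates[ord]
  supra <- rates > 0 & currents > 0
  if (sum(supra) < 4)
    stop("need at least 4 suprathreshold (rate > 0) steps to fit the F-I curve",
         call. = FALSE)
  I <- currents[supra]; r <- rates[supra]
  zeroI <- currents[rates == 0 & currents >= 0]
  halfStep <- if (length(I) > 1) min(diff(I)) / 2 else I[1] / 4
  rheo0 <- if (length(zeroI)) max(zeroI) + halfStep else I[1] / 2
  rheo0 <- min(max(rheo0, 1e-3), I[1] * 0.999)
  gain0 <- (r[2] - r[1]) / (log(I[2]) - log(I[1]))
  if (!is.finite(gain0) || gain0 <= 0) gain0 <- max(r) / log(max(I) / rheo0)
  fit <- minpack.lm::nlsLM(
    r ~ gain * log(I / rheobase),
    start = list(gain = gain0, rheobase = rheo0),
    lower = c(1e-6, 1e-6), upper = c(Inf, I[1] * (1 - 1e-9)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)))
    stop("F-I fit did not converge; coefficients: ",
         paste(signif(cf, 4), collapse = ", "), call. = FALSE)
  maxRate <- max(rates)
  injCurr50 <- .injCurr50(currents, rates, maxRate / 2)
  new("FICurveFit", gain = unname(cf["gain"]),
      rheobase = unname(cf["rheobase"]), maxRate = maxRate,
      injCurr50 = injCurr50,
      rates = data.frame(current = currents, rate = rates),
      fitRms = sqrt(mean(stats::resid(fit)^2)))
}

## Smallest current at which the piecewise-linear measured curve reaches
## `target`.
.injCurr50 <- function(currents, rates, target) {
  for (i in seq_along(currents)) {
    if (rates[i] >= target) {
      if (i == 1) return(currents[1])
      frac <- (target - rates[i - 1]) / (rates[i] - rates[i - 1])
      return(currents[i - 1] + frac * (currents[i] - currents[i - 1]))
    }
  }
  NA_real_
}

#' F-I curve fit of a current-step experiment
#'
#' Counts spikes ([detectSpikes()]) within the step window of every sweep
#' (spikes after step offset, e.g. rebound spikes, are not counted),
#' converts counts to rates by the step duration, and fits the logarithmic
#' F-I model via [fiFitRates()].
#'
#' @param sweeps a [SweepSet-class].
#' @param threshold spike detection threshold (mV).
#' @return A [FICurveFit-class].
#' @export
fiFit <- function(sweeps, threshold = 0) {
  stopifnot(is(sweeps, "SweepSet"))
  onset <- sweeps@stepOnset
  offset <- onset + sweeps@stepDuration
  rates <- vapply(sweeps@traces, function(tr) {
    st <- spikeTimes(detectSpikes(tr, threshold = threshold))
    sum(st >= onset & st < offset) / sweeps@stepDuration
  }, numeric(1))
  fiFitRates(sweeps@currents, rates)
}
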