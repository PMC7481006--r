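#' @include RcppExports.R
NULL

.TRACE_UNITS <- c("mV", "pA", "uV")
.TRACE_KINDS <- c("intracellular_V", "intracellular_I", "juxtacellular_V", "lfp")

#' Uniformly sampled recording channel
#'
#' A `Trace` holds one uniformly sampled channel -- an intracellular voltage
#' or current, a juxtacellular voltage, or a local field potential -- together
#' with its sampling rate, physical units and start time. It is the universal
#' input of every analysis in the package. Internal unit conventions are
#' seconds, mV, pA and uV; all time intervals are half-open `[start, end)`.
#'
#' @slot samples numeric vector of samples (finite).
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot units one of `"mV"`, `"pA"`, `"uV"`.
#' @slot kind one of `"intracellular_V"`, `"intracellular_I"`,
#'   `"juxtacellular_V"`, `"lfp"`.
#' @slot t0 start time in seconds (default 0).
#' @export
setClass("Trace",
  representation(samples = "numeric", samplingRate = "numeric",
                 units = "character", kind = "character", t0 = "numeric"),
  prototype(t0 = 0))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@samples) < 1)
    msg <- c(msg, "samples must be non-empty")
  if (anyNA(object@samples) || !all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (!(object@units %in% .TRACE_UNITS))
    msg <- c(msg, sprintf("units must be one of %s",
                          paste(.TRACE_UNITS, collapse = ", ")))
  if (!(object@kind %in% .TRACE_KINDS))
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.TRACE_KINDS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Trace
#'
#' @param samples numeric samples.
#' @param samplingRate sampling rate in Hz.
#' @param units physical units of the samples (`"mV"`, `"pA"` or `"uV"`).
#' @param kind channel kind (`"intracellular_V"`, `"intracellular_I"`,
#'   `"juxtacellular_V"` or `"lfp"`).
#' @param t0 start time in seconds.
#' @return A [Trace-class] object.
#' @examples
#' tr <- Trace(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), 1000, "uV", "lfp")
#' duration(tr)
#' @export
Trace <- function(samples, samplingRate, units, kind, t0 = 0) {
  new("Trace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      units = units, kind = kind, t0 = as.numeric(t0))
}

#' Spike (event) train
#'
#' Ordered event times over a known recording duration; the output of spike
#' detection and the input of rate, phase-locking and spike-triggered
#' analyses. Times are relative to the recording start (seconds) and must lie
#' in `[0, duration)`.
#'
#' @slot times strictly increasing spike times in seconds.
#' @slot duration recording duration in seconds.
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", duration = "numeric"))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (length(object@duration) != 1 || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number")
  if (length(object@times)) {
    if (anyNA(object@times) || !all(is.finite(object@times)))
      msg <- c(msg, "times must be finite")
    else {
      if (is.unsorted(object@times, strictly = TRUE))
        msg <- c(msg, "times must be strictly increasing")
      if (min(object@times) < 0 || max(object@times) >= object@duration)
        msg <- c(msg, "times must lie in [0, duration)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times strictly increasing spike times in seconds.
#' @param duration recording duration in seconds.
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(times, duration) {
  new("SpikeTrain", times = as.numeric(times), duration = as.numeric(duration))
}

#' Instantaneous phase of a band-passed signal
#'
#' Phase series aligned to the time base of the trace it was computed from.
#' Phase 0 is the positive peak of the band-passed oscillation and phase
#' increases with time. The first and last `edgeSamples` samples (one period
#' of the band's lower edge) are transient-contaminated and are excluded from
#' spike-phase lookup.
#'
#' @slot phases phase in radians, in (-pi, pi].
#' @slot samplingRate Hz of the source trace.
#' @slot t0 start time (s) of the source trace.
#' @slot band numeric length-2, the (f_lo, f_hi) band in Hz.
#' @slot edgeSamples number of unreliable samples at each end.
#' @export
setClass("PhaseSeries",
  representation(phases = "numeric", samplingRate = "numeric",
                 t0 = "numeric", band = "numeric", edgeSamples = "integer"))

setValidity("PhaseSeries", function(object) {
  msg <- character()
  if (length(object@band) != 2 || object@band[1] <= 0 ||
      object@band[2] <= object@band[1])
    msg <- c(msg, "band must satisfy 0 < f_lo < f_hi")
  if (object@band[2] > object@samplingRate / 2 + 1e-9)
    msg <- c(msg, "band upper edge exceeds Nyquist")
  if (length(msg)) msg else TRUE
})

#' Power spectral density
#'
#' One-sided Welch power spectral density (Hann window, averaged overlapping
#' periodograms). Power is a per-Hz density unless `normalized` is `TRUE`, in
#' which case it has been rescaled to sum to 1 over `normBand`.
#'
#' @slot freqs frequencies (Hz), ascending from 0.
#' @slot power spectral power (density, or normalized fraction).
#' @slot windowLen window length in samples.
#' @slot overlapFraction fractional segment overlap.
#' @slot normalized logical; was the power normalized over a band?
#' @slot normBand the normalization band (Hz), or numeric(0).
#' @export
setClass("Spectrum",
  representation(freqs = "numeric", power = "numeric", windowLen = "numeric",
                 overlapFraction = "numeric", normalized = "logical",
                 normBand = "numeric"),
  prototype(normalized = FALSE, normBand = numeric(0)))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power lengths differ")
  if (length(object@freqs) && (is.unsorted(object@freqs) || object@freqs[1] < 0))
    msg <- c(msg, "freqs must ascend from >= 0")
  if (any(object@power < -1e-12))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Current-step sweep set
#'
#' A current-clamp excitability experiment: one voltage trace per injected
#' current step, sharing a sampling rate and the step timing (2 s steps in
#' the standard protocol).
#'
#' @slot currents injected currents in pA, one per sweep, distinct.
#' @slot traces list of [Trace-class] (`intracellular_V`), parallel to
#'   `currents`.
#' @slot stepOnset step onset in seconds.
#' @slot stepDuration step duration in seconds.
#' @export
setClass("SweepSet",
  representation(currents = "numeric", traces = "list",
                 stepOnset = "numeric", stepDuration = "numeric"))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (length(object@currents) != length(object@traces))
    msg <- c(msg, "currents and traces lengths differ")
  if (anyDuplicated(object@currents))
    msg <- c(msg, "injected currents must be distinct")
  if (!all(vapply(object@traces, function(tr) is(tr, "Trace"), logical(1))))
    msg <- c(msg, "traces must all be Trace objects")
  else {
    rates <- vapply(object@traces, function(tr) tr@samplingRate, numeric(1))
    if (length(unique(rates)) > 1)
      msg <- c(msg, "all sweeps must share one sampling rate")
    durs <- vapply(object@traces, duration, numeric(1))
    if (any(object@stepOnset + object@stepDuration > durs + 1e-9))
      msg <- c(msg, "step window must fall within every sweep")
  }
  if (object@stepOnset < 0 || object@stepDuration <= 0)
    msg <- c(msg, "step onset/duration invalid")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepSet
#'
#' @param currents injected currents (pA).
#' @param traces list of voltage [Trace-class] objects, parallel to `currents`.
#' @param stepOnset step onset (s).
#' @param stepDuration step duration (s); 2 s in the standard protocol.
#' @return A [SweepSet-class].
#' @export
SweepSet <- function(currents, traces, stepOnset, stepDuration = 2) {
  new("SweepSet", currents = as.numeric(currents), traces = traces,
      stepOnset = as.numeric(stepOnset), stepDuration = as.numeric(stepDuration))
}

#' Paired-recording synaptic train sweeps
#'
#' Postsynaptic current sweeps evoked by a train of 5 presynaptic action
#' potentials at 50 Hz (20 ms inter-stimulus interval), aligned to the
#' stimulus clock.
#'
#' @slot sweeps list of [Trace-class] (`intracellular_I`, pA).
#' @slot stimTimes the 5 stimulus times (s), strictly increasing, equal ISI.
#' @slot baselineWindow `c(start, end)` in seconds, stimulus-free.
#' @slot polarity `"inward"` (negative-going responses) or `"outward"`.
#' @export
setClass("PairedTrainRecording",
  representation(sweeps = "list", stimTimes = "numeric",
                 baselineWindow = "numeric", polarity = "character"))

setValidity("PairedTrainRecording", function(object) {
  msg <- character()
  st <- object@stimTimes
  if (length(st) < 1 || is.unsorted(st, strictly = TRUE))
    msg <- c(msg, "stimTimes must be strictly increasing")
  else if (length(st) > 2) {
    isi <- diff(st)
    if (max(abs(isi - isi[1])) > 1e-9)
      msg <- c(msg, "stimTimes must be equally spaced")
  }
  if (!(object@polarity %in% c("inward", "outward")))
    msg <- c(msg, "polarity must be 'inward' or 'outward'")
  if (length(object@baselineWindow) != 2 ||
      object@baselineWindow[2] <= object@baselineWindow[1])
    msg <- c(msg, "baselineWindow must be c(start, end), start < end")
  if (length(st) && length(object@baselineWindow) == 2 &&
      any(st >= object@baselineWindow[1] & st < object@baselineWindow[2]))
    msg <- c(msg, "baseline window must be free of stimuli")
  if (!all(vapply(object@sweeps, function(tr) is(tr, "Trace"), logical(1))))
    msg <- c(msg, "sweeps must all be Trace objects")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedTrainRecording
#'
#' @param sweeps list of current [Trace-class] sweeps (pA).
#' @param stimTimes presynaptic stimulus times (s), 5 at 50 Hz in the
#'   standard protocol.
#' @param baselineWindow stimulus-free `c(start, end)` window (s).
#' @param polarity `"inward"` or `"outward"`.
#' @return A [PairedTrainRecording-class].
#' @export
PairedTrainRecording <- function(sweeps, stimTimes, baselineWindow,
                                 polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  new("PairedTrainRecording", sweeps = sweeps,
      stimTimes = as.numeric(stimTimes),
      baselineWindow = as.numeric(baselineWindow), polarity = polarity)
}

#' Passive membrane properties
#'
#' @slot vRest resting membrane potential (mV).
#' @slot ri input resistance (MOhm, > 0).
#' @slot tauMemb membrane time constant (ms, > 0).
#' @export
setClass("PassiveProperties",
  representation(vRest = "numeric", ri = "numeric", tauMemb = "numeric"))

setValidity("PassiveProperties", function(object) {
  msg <- character()
  if (object@ri <= 0) msg <- c(msg, "ri must be positive")
  if (object@tauMemb <= 0) msg <- c(msg, "tauMemb must be positive")
  if (length(msg)) msg else TRUE
})

#' Single action-potential features
#'
#' Threshold is the membrane potential at which dV/dt first exceeds the
#' criterion (10 mV/ms by default); amplitude is peak minus threshold;
#' half-width is the spike width at 50% of the amplitude.
#'
#' @slot threshold mV.
#' @slot amplitude mV (peak - threshold).
#' @slot halfWidth ms (> 0).
#' @slot peak mV.
#' @export
setClass("APFeatures",
  representation(threshold = "numeric", amplitude = "numeric",
                 halfWidth = "numeric", peak = "numeric"))

setValidity("APFeatures", function(object) {
  msg <- character()
  if (abs(object@amplitude - (object@peak - object@threshold)) > 1e-9)
    msg <- c(msg, "amplitude must equal peak - threshold")
  if (object@halfWidth <= 0) msg <- c(msg, "halfWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Logarithmic F-I curve fit
#'
#' Summary of an excitability experiment under the model
#' `f(I) = gain * ln(I / rheobase)`: the fitted gain (Hz) and rheobase (pA),
#' the maximal observed spiking rate, the current needed to reach half the
#' maximal rate (from the measured curve, by linear interpolation), the
#' per-step measured rates, and the fit RMS residual.
#'
#' @slot gain Hz.
#' @slot rheobase pA (> 0; the model predicts f(rheobase) = 0).
#' @slot maxRate Hz, maximum observed rate.
#' @slot injCurr50 pA, current to reach 50% of maxRate.
#' @slot rates data.frame with columns `current` (pA) and `rate` (Hz).
#' @slot fitRms Hz.
#' @export
setClass("FICurveFit",
  representation(gain = "numeric", rheobase = "numeric", maxRate = "numeric",
                 injCurr50 = "numeric", rates = "data.frame",
                 fitRms = "numeric"))

setValidity("FICurveFit", function(object) {
  if (object@rheobase <= 0) "rheobase must be positive" else TRUE
})

#' Unitary synaptic train response statistics
#'
#' Per-pulse measures of a 5-pulse unitary synaptic train: trial-mean
#' amplitudes (from the mean trace; `amp[1]` is `NA` when every trial is a
#' failure), success-only amplitudes, per-pulse failure rates, total
#' rectified charge, first-response kinetics and short-term plasticity
#' ratios.
#'
#' @slot amp per-pulse amplitude (pA) from the mean trace.
#' @slot ampSuccesses per-pulse mean amplitude over non-failure trials (pA).
#' @slot failureRate per-pulse fraction of failure trials, in [0, 1].
#' @slot q total train charge (pC, >= 0).
#' @slot riseTime 20-80% rise time of the first-pulse mean response (ms).
#' @slot decayTau single-exponential decay constant of the last response (ms).
#' @slot stpRatio per-pulse `amp / amp[1]` (`stpRatio[1]` is 1).
#' @slot nSweeps number of sweeps analyzed.
#' @export
setClass("TrainResponseStats",
  representation(amp = "numeric", ampSuccesses = "numeric",
                 failureRate = "numeric", q = "numeric", riseTime = "numeric",
                 decayTau = "numeric", stpRatio = "numeric",
                 nSweeps = "integer"))

setValidity("TrainResponseStats", function(object) {
  msg <- character()
  if (any(object@failureRate < -1e-12 | object@failureRate > 1 + 1e-12))
    msg <- c(msg, "failureRate must lie in [0, 1]")
  if (!is.na(object@q) && object@q < 0)
    msg <- c(msg, "charge must be non-negative")
  if (length(msg)) msg else TRUE
})

#' UP/DOWN state evidence series
#'
#' Combined state-evidence variable at the LFP analysis rate: the z-scored
#' log high-frequency (20-100 Hz) power plus the z-scored cosine of the slow
#' (< 4 Hz) oscillation phase relative to the phase of maximal
#' high-frequency power.
#'
#' @slot sComb combined evidence series.
#' @slot samplingRate Hz.
#' @slot t0 start time (s).
#' @slot slowPhaseTerm the z-scored slow-phase component.
#' @slot highFreqTerm the z-scored log-power component.
#' @slot window power smoothing window (ms).
#' @export
setClass("StateEvidence",
  representation(sComb = "numeric", samplingRate = "numeric", t0 = "numeric",
                 slowPhaseTerm = "numeric", highFreqTerm = "numeric",
                 window = "numeric"))

setValidity("StateEvidence", function(object) {
  msg <- character()
  if (!all(is.finite(object@sComb))) msg <- c(msg, "sComb must be finite")
  if (length(object@sComb) != length(object@slowPhaseTerm) ||
      length(object@sComb) != length(object@highFreqTerm))
    msg <- c(msg, "component series must match sComb length")
  if (length(msg)) msg else TRUE
})

#' Three-component Gaussian mixture fit of state evidence
#'
#' Components are labeled by ascending mean: DOWN, INTERMEDIATE, UP. The
#' classification thresholds are `thUp = mu_UP - 3 sd_UP` and
#' `thDown = mu_DOWN + 3 sd_DOWN` (multiplier and sidedness configurable in
#' [detectStates()]).
#'
#' @slot means component means, ascending (DOWN, INTERMEDIATE, UP).
#' @slot sds component standard deviations (> 0).
#' @slot weights mixing weights (sum to 1).
#' @slot thUp UP classification threshold.
#' @slot thDown DOWN classification threshold.
#' @export
setClass("GMMFit",
  representation(means = "numeric", sds = "numeric", weights = "numeric",
                 thUp = "numeric", thDown = "numeric"))

setValidity("GMMFit", function(object) {
  msg <- character()
  if (is.unsorted(object@means)) msg <- c(msg, "means must ascend")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' UP/DOWN/INTERMEDIATE state segmentation
#'
#' Non-overlapping labeled intervals partitioning a recording. Every UP or
#' DOWN interval is at least `minDuration` ms long, and consecutive
#' same-label intervals are at least `minInterval` ms apart (shorter gaps
#' having been merged).
#'
#' @slot intervals data.frame with columns `start` (s), `end` (s), `label`
#'   (one of `"UP"`, `"DOWN"`, `"INTERMEDIATE"`).
#' @slot minInterval ms.
#' @slot minDuration ms.
#' @slot recordDuration total recording span (s).
#' @export
setClass("StateSegmentation",
  representation(intervals = "data.frame", minInterval = "numeric",
                 minDuration = "numeric", recordDuration = "numeric"))

setValidity("StateSegmentation", function(object) {
  iv <- object@intervals
  msg <- character()
  if (!all(c("start", "end", "label") %in% names(iv)))
    msg <- c(msg, "intervals needs columns start, end, label")
  else if (nrow(iv)) {
    if (any(iv$end <= iv$start)) msg <- c(msg, "empty or inverted interval")
    if (is.unsorted(iv$start)) msg <- c(msg, "intervals must ascend")
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-9))
      msg <- c(msg, "intervals must not overlap")
    if (!all(iv$label %in% c("UP", "DOWN", "INTERMEDIATE")))
      msg <- c(msg, "labels must be UP, DOWN or INTERMEDIATE")
    ud <- iv$label %in% c("UP", "DOWN")
    if (any((iv$end[ud] - iv$start[ud]) * 1000 < object@minDuration - 1e-6))
      msg <- c(msg, "UP/DOWN interval shorter than minDuration")
  }
  if (length(msg)) msg else TRUE
})

#' Spike-triggered LFP result
#'
#' Mean LFP waveform aligned on spike peak times over a +/- `halfWindow`
#' window, its low-pass filtered version, peak-to-peak amplitudes of both,
#' and the Welch spectrum of the mean waveform.
#'
#' @slot waveform raw mean waveform (uV), length `2*halfWindow*rate + 1`.
#' @slot waveformFiltered low-pass filtered mean waveform (uV).
#' @slot lags lag times (s) relative to the spike.
#' @slot samplingRate Hz.
#' @slot peakToPeak uV, on the filtered waveform (>= 0).
#' @slot peakToPeakRaw uV, on the raw waveform.
#' @slot spectrum [Spectrum-class] of the mean waveform.
#' @slot nSpikes spikes averaged.
#' @slot nSkipped spikes skipped for lacking a full window.
#' @export
setClass("StLFPResult",
  representation(waveform = "numeric", waveformFiltered = "numeric",
                 lags = "numeric", samplingRate = "numeric",
                 peakToPeak = "numeric", peakToPeakRaw = "numeric",
                 spectrum = "Spectrum", nSpikes = "integer",
                 nSkipped = "integer"))

setValidity("StLFPResult", function(object) {
  msg <- character()
  if (object@peakToPeak < 0) msg <- c(msg, "peakToPeak must be >= 0")
  if (length(object@waveform) != length(object@lags))
    msg <- c(msg, "waveform and lags lengths differ")
  if (length(msg)) msg else TRUE
})

#' Two-group comparison of a cohort metric
#'
#' Result of the normality-gated two-group comparison: Shapiro-Wilk
#' normality is assessed per group; if both groups are compatible with
#' normality a two-tailed Student's t test is used, otherwise a two-tailed
#' Mann-Whitney U test.
#'
#' @slot metric metric name.
#' @slot groups the two group labels.
#' @slot summary data.frame of per-group median, Q1, Q3, n.
#' @slot test `"t_test"` or `"mann_whitney"`.
#' @slot pValue two-sided p value.
#' @slot shapiroP per-group Shapiro-Wilk p values.
#' @export
setClass("GroupComparison",
  representation(metric = "character", groups = "character",
                 summary = "data.frame", test = "character",
                 pValue = "numeric", shapiroP = "numeric"))

setValidity("GroupComparison", function(object) {
  if (!(object@test %in% c("t_test", "mann_whitney")))
    "test must be 't_test' or 'mann_whitney'" else TRUE
})
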