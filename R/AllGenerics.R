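#' @include AllClasses.R
NULL

#' Accessors for the core recording classes
#'
#' `samples()`, `samplingRate()`, `traceUnits()`, `traceKind()` and
#' `startTime()` read the corresponding [Trace-class] slots; `duration()`
#' gives the spanned time (s) of a trace or spike train; `spikeTimes()` and
#' `nSpikes()` read a [SpikeTrain-class]; `traceTimes()` gives the sample
#' time base of a trace; `stateIntervals()` the interval table of a
#' [StateSegmentation-class].
#'
#' @param x the object.
#' @return The slot value (or derived vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))
#' @rdname accessors
#' @export
setGeneric("traceKind", function(x) standardGeneric("traceKind"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("stateIntervals", function(x) standardGeneric("stateIntervals"))

#' @rdname accessors
#' @export
setMethod("samples", "Trace", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Trace", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "PhaseSeries", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "StateEvidence", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("traceUnits", "Trace", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("traceKind", "Trace", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("startTime", "Trace", function(x) x@t0)
#' @rdname accessors
#' @export
setMethod("duration", "Trace",
          function(x) length(x@samples) / x@samplingRate)
#' @rdname accessors
#' @export
setMethod("duration", "SpikeTrain", function(x) x@duration)
#' @rdname accessors
#' @export
setMethod("traceTimes", "Trace",
          function(x) x@t0 + (seq_along(x@samples) - 1) / x@samplingRate)
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))
#' @rdname accessors
#' @export
setMethod("stateIntervals", "StateSegmentation", function(x) x@intervals)

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %s [%s], %d samples @ %g Hz (%.6g s), t0 = %g s\n",
              object@kind, object@units, length(object@samples),
              object@samplingRate, duration(object), object@t0))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes over %.6g s (%.4g Hz)\n",
              length(object@times), object@duration,
              length(object@times) / object@duration))
})

setMethod("show", "PhaseSeries", function(object) {
  cat(sprintf(
    "PhaseSeries: band %g-%g Hz, %d samples @ %g Hz (%d edge samples/side)\n",
    object@band[1], object@band[2], length(object@phases),
    object@samplingRate, object@edgeSamples))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins, 0-%.4g Hz, window %d samples%s\n",
              length(object@freqs), max(object@freqs), object@windowLen,
              if (object@normalized)
                sprintf(", normalized over %g-%g Hz",
                        object@normBand[1], object@normBand[2]) else ""))
})

setMethod("show", "SweepSet", function(object) {
  cat(sprintf(
    "SweepSet: %d sweeps, %g to %g pA, step %g s at t = %g s\n",
    length(object@currents), min(object@currents), max(object@currents),
    object@stepDuration, object@stepOnset))
})

setMethod("show", "PairedTrainRecording", function(object) {
  cat(sprintf(
    "PairedTrainRecording: %d sweeps, %d stimuli (ISI %g ms), %s responses\n",
    length(object@sweeps), length(object@stimTimes),
    if (length(object@stimTimes) > 1) 1000 * diff(object@stimTimes)[1]
    else NA_real_, object@polarity))
})

setMethod("show", "PassiveProperties", function(object) {
  cat(sprintf(
    "PassiveProperties: Vrest %.2f mV, Ri %.1f MOhm, tau %.2f ms\n",
    object@vRest, object@ri, object@tauMemb))
})

setMethod("show", "APFeatures", function(object) {
  cat(sprintf(
    "APFeatures: threshold %.2f mV, amplitude %.2f mV, half-width %.3f ms\n",
    object@threshold, object@amplitude, object@halfWidth))
})

setMethod("show", "FICurveFit", function(object) {
  cat(sprintf(
    paste0("FICurveFit: gain %.2f Hz, rheobase %.2f pA, max rate %.2f Hz,\n",
           "  InjCurr50 %.2f pA, RMS %.3g Hz (%d suprathreshold steps)\n"),
    object@gain, object@rheobase, object@maxRate, object@injCurr50,
    object@fitRms, sum(object@rates$rate > 0)))
})

setMethod("show", "TrainResponseStats", function(object) {
  cat(sprintf(
    paste0("TrainResponseStats (%d sweeps): amp1 %.2f pA, failure1 %.2f, ",
           "Q %.3f pC,\n  rise %.2f ms, decay %.2f ms, STP ratios: %s\n"),
    object@nSweeps, object@amp[1], object@failureRate[1], object@q,
    object@riseTime, object@decayTau,
    paste(sprintf("%.2f", object@stpRatio), collapse = " ")))
})

setMethod("show", "StateEvidence", function(object) {
  cat(sprintf("StateEvidence: %d samples @ %g Hz, smoothing window %g ms\n",
              length(object@sComb), object@samplingRate, object@window))
})

setMethod("show", "GMMFit", function(object) {
  cat(sprintf(
    paste0("GMMFit: means %.3f/%.3f/%.3f (DOWN/INT/UP), ",
           "thresholds DOWN < %.3f, UP > %.3f\n"),
    object@means[1], object@means[2], object@means[3],
    object@thDown, object@thUp))
})

setMethod("show", "StateSegmentation", function(object) {
  iv <- object@intervals
  cat(sprintf(
    "StateSegmentation over %.6g s: %d UP, %d DOWN, %d INTERMEDIATE\n",
    object@recordDuration, sum(iv$label == "UP"), sum(iv$label == "DOWN"),
    sum(iv$label == "INTERMEDIATE")))
})

setMethod("show", "StLFPResult", function(object) {
  cat(sprintf(
    "StLFPResult: %d spikes, peak-to-peak %.2f uV (raw %.2f), %d skipped\n",
    object@nSpikes, object@peakToPeak, object@peakToPeakRaw,
    object@nSkipped))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison '%s': %s vs %s, %s, p = %.4g\n",
              object@metric, object@groups[1], object@groups[2],
              object@test, object@pValue))
  print(object@summary, row.names = FALSE)
})
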