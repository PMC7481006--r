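#' @include AllClasses.R
NULL

#' Juxtacellular spike detection
#'
#' High-pass filters the juxtacellular voltage (5 Hz cutoff, removing the
#' slow field component) and detects spikes as peaks of suprathreshold
#' excursions above 1.5 mV, with a refractory period. An empty train is a
#' valid result.
#'
#' @param trace a juxtacellular voltage [Trace-class] (mV).
#' @param hpCutoff high-pass cutoff (Hz).
#' @param threshold detection threshold (mV) on the filtered trace.
#' @param refractory refractory period (ms).
#' @return A [SpikeTrain-class].
#' @export
detectSpikesJuxta <- function(trace, hpCutoff = 5, threshold = 1.5,
                              refractory = 2) {
  stopifnot(is(trace, "Trace"))
  detectSpikes(highpass(trace, hpCutoff), threshold = threshold,
               refractory = refractory)
}

#' Mean firing rate
#'
#' Total number of spikes divided by the recording duration.
#'
#' @param spikes a [SpikeTrain-class].
#' @return Rate in Hz.
#' @export
firingRate <- function(spikes) {
  stopifnot(is(spikes, "SpikeTrain"))
  nSpikes(spikes) / duration(spikes)
}

#' Spike-triggered LFP
#'
#' Averages LFP segments of +/- `halfWindowMs` around each spike peak time.
#' Spikes without a full window inside the LFP are skipped (their count is
#' reported). The peak-to-peak amplitude is measured on the low-pass
#' filtered (100 Hz) mean waveform; the raw-waveform value is reported
#' alongside. The spectrum of the mean waveform uses a Welch window
#' shortened to the largest power of two not exceeding the segment length.
#'
#' @param lfp an LFP [Trace-class] at the analysis rate.
#' @param spikes a [SpikeTrain-class] on the same time base.
#' @param halfWindowMs half-window (ms).
#' @param smoothCutoff low-pass cutoff (Hz) for the filtered waveform.
#' @return An [StLFPResult-class].
#' @export
spikeTriggeredLFP <- function(lfp, spikes, halfWindowMs = 100,
                              smoothCutoff = 100) {
  stopifnot(is(lfp, "Trace"), is(spikes, "SpikeTrain"))
  fs <- lfp@samplingRate
  n <- length(lfp@samples)
  half <- as.integer(round(halfWindowMs / 1000 * fs))
  centers <- .sampleIndex(spikeTimes(spikes), fs, lfp@t0)
  ok <- centers - half >= 1L & centers + half <= n
  nSkipped <- sum(!ok)
  centers <- centers[ok]
  if (!length(centers))
    stop("no spike has a full LFP window; spike-triggered LFP undefined",
         call. = FALSE)
  offs <- -half:half
  ## accumulate the mean waveform without materialising the segment matrix
  wf <- numeric(length(offs))
  for (c0 in centers) wf <- wf + lfp@samples[c0 + offs]
  wf <- wf / length(centers)
  wfTrace <- new("Trace", samples = wf, samplingRate = fs,
                 units = lfp@units, kind = "lfp", t0 = -half / fs)
  wfF <- if (smoothCutoff < fs / 2) lowpass(wfTrace, smoothCutoff)@samples
         else wf
  wlen <- 2^floor(log2(length(wf)))
  spec <- welchPsd(wfTrace, windowLen = wlen, overlap = 0.5)
  new("StLFPResult", waveform = wf, waveformFiltered = wfF,
      lags = offs / fs, samplingRate = fs,
      peakToPeak = max(wfF) - min(wfF),
      peakToPeakRaw = max(wf) - min(wf), spectrum = spec,
      nSpikes = length(centers), nSkipped = as.integer(nSkipped))
}
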