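#' @include AllClasses.R
NULL

#' Pairwise phase consistency
#'
#' The PPC of a set of spike phases is the average cosine of the phase
#' difference over all spike pairs,
#' `2/(N(N-1)) * sum_{i<j} cos(theta_i - theta_j)`, computed via the
#' algebraically identical closed form `(N R^2 - 1) / (N - 1)` where `R` is
#' the mean resultant length. The PPC is an unbiased estimator of the
#' squared population resultant length: it is 0 in expectation for uniform
#' phases, 1 when all phases are equal, and bounded below by `-1/(N-1)`. It
#' is invariant to a global phase rotation and to spike reordering.
#'
#' @param phases spike phases in radians (N >= 2).
#' @return The PPC value, in `[-1/(N-1), 1]`.
#' @examples
#' ppc(c(0, 0, 0))                    # 1
#' ppc(c(0, pi / 2, pi, 3 * pi / 2))  # -1/3
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2)
    stop("PPC is undefined for fewer than 2 spikes", call. = FALSE)
  R2 <- Mod(mean(exp(1i * phases)))^2
  (n * R2 - 1) / (n - 1)
}

#' Band-wise spike-field pairwise phase consistency
#'
#' For each frequency band, computes the instantaneous LFP phase
#' ([hilbertPhase()]), looks up the phase at each spike time (nearest LFP
#' sample; edge-contaminated samples excluded), and returns the PPC together
#' with the spike count and a reliability flag (at least 250 spikes are
#' required for a reliable PPC estimate).
#'
#' @param lfp an LFP [Trace-class] at the analysis rate (typically decimated
#'   to 1 kHz and low-passed at 100 Hz upstream).
#' @param spikes a [SpikeTrain-class] on the same time base.
#' @param bands list of `c(fLo, fHi)` bands (Hz); defaults to the standard
#'   4-10, 10-20, 20-40, 40-60, 60-80, 80-100 Hz analysis bands.
#' @param minSpikes reliability threshold on the spike count.
#' @return A data.frame with columns `fLo`, `fHi`, `ppc`, `nSpikes`,
#'   `reliable`.
#' @export
bandPPC <- function(lfp, spikes,
                    bands = list(c(4, 10), c(10, 20), c(20, 40),
                                 c(40, 60), c(60, 80), c(80, 100)),
                    minSpikes = 250) {
  stopifnot(is(lfp, "Trace"), is(spikes, "SpikeTrain"))
  fs <- lfp@samplingRate
  n <- length(lfp@samples)
  idx <- .sampleIndex(spikeTimes(spikes), fs, lfp@t0)
  dropped <- idx < 1L | idx > n
  if (any(dropped)) {
    warning(sprintf("%d spike(s) outside the LFP span dropped", sum(dropped)))
    idx <- idx[!dropped]
  }
  X <- stats::fft(lfp@samples)   # shared across bands
  res <- lapply(bands, function(band) {
    phSeries <- Arg(.analyticBand(lfp, band, X = X))
    edge <- min(as.integer(ceiling(3 * fs / band[1])), n %/% 2L)
    ok <- idx > edge & idx <= n - edge
    phases <- phSeries[idx[ok]]
    data.frame(fLo = band[1], fHi = band[2],
               ppc = if (length(phases) >= 2) ppc(phases) else NA_real_,
               nSpikes = length(phases),
               reliable = length(phases) >= minSpikes)
  })
  do.call(rbind, res)
}

#' Spike phases in one band
#'
#' Phase of the LFP at each spike time (nearest sample at the LFP rate;
#' spikes in the edge-contaminated margins or outside the LFP are dropped).
#'
#' @inheritParams bandPPC
#' @param band `c(fLo, fHi)` in Hz.
#' @return Numeric vector of phases (radians).
#' @export
spikePhases <- function(lfp, spikes, band) {
  stopifnot(is(lfp, "Trace"), is(spikes, "SpikeTrain"))
  ph <- hilbertPhase(lfp, band)
  n <- length(ph@phases)
  idx <- .sampleIndex(spikeTimes(spikes), lfp@samplingRate, lfp@t0)
  idx <- idx[idx > ph@edgeSamples & idx <= n - ph@edgeSamples]
  ph@phases[idx]
}
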