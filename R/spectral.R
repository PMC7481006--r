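#' @include AllClasses.R
NULL

## Analytic signal by the FFT method: zero the negative frequencies, double
## the positive ones, keep DC (and Nyquist for even n) unchanged.
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Averaged Hann-windowed periodograms (window length 4096 samples and 50%
#' overlap by default). Power is a one-sided per-Hz density, so that the
#' integral of the density over frequency recovers the signal variance
#' (Parseval); segment means are removed before windowing. When
#' `normalizeBand` is given the power is instead rescaled to sum to 1 over
#' that band ("normalized PSD").
#'
#' @param trace a [Trace-class]; must be at least one window long.
#' @param windowLen window length in samples.
#' @param overlap fractional overlap between segments, in [0, 1).
#' @param normalizeBand optional `c(fLo, fHi)` (Hz) normalization band.
#' @return A [Spectrum-class].
#' @examples
#' t <- seq(0, 60, by = 1e-3)[-1]
#' tr <- Trace(sin(2 * pi * 40 * t), 1000, "uV", "lfp")
#' sp <- welchPsd(tr)   # peak at 40 Hz
#' @export
welchPsd <- function(trace, windowLen = 4096, overlap = 0.5,
                     normalizeBand = NULL) {
  stopifnot(is(trace, "Trace"))
  x <- trace@samples
  fs <- trace@samplingRate
  windowLen <- as.integer(windowLen)
  if (length(x) < windowLen)
    stop(sprintf(paste0("trace (%d samples) is shorter than one window ",
                        "(%d samples); reduce windowLen"),
                 length(x), windowLen), call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must lie in [0, 1)", call. = FALSE)
  step <- max(1L, as.integer(round(windowLen * (1 - overlap))))
  starts <- seq(1L, length(x) - windowLen + 1L, by = step)
  k <- seq_len(windowLen) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / windowLen))     # periodic Hann
  U <- sum(w^2)
  nf <- windowLen %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + windowLen - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2)
  }
  psd <- acc / (length(starts) * fs * U)
  ## one-sided: double everything except DC (and Nyquist when n even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (windowLen %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  freqs <- (seq_len(nf) - 1L) * fs / windowLen
  normalized <- FALSE
  normBand <- numeric(0)
  if (!is.null(normalizeBand)) {
    stopifnot(length(normalizeBand) == 2)
    inBand <- freqs >= normalizeBand[1] & freqs <= normalizeBand[2]
    tot <- sum(psd[inBand])
    if (tot <= 0) stop("no power in the normalization band", call. = FALSE)
    psd <- psd / tot
    normalized <- TRUE
    normBand <- as.numeric(normalizeBand)
  }
  new("Spectrum", freqs = freqs, power = psd, windowLen = windowLen,
      overlapFraction = overlap, normalized = normalized, normBand = normBand)
}

## Squared magnitude response of a zero-phase (forward-backward) Butterworth
## band filter, evaluated at the n FFT bin frequencies. Cascaded low+high
## designs are used when the lower edge is a tiny fraction of the rate, as
## in the time-domain path.
.bandMag2 <- function(band, fs, n) {
  ## closed-form squared magnitude of bilinear-transformed Butterworth
  ## designs (what signal::butter produces), evaluated at the FFT bins
  w <- 2 * pi * (seq_len(n) - 1) / n
  v <- tan(w / 2)
  lowMag2 <- function(fc, ord) {
    vc <- tan(pi * fc / fs)
    1 / (1 + (v / vc)^(2 * ord))
  }
  highMag2 <- function(fc, ord) {
    vc <- tan(pi * fc / fs)
    m <- 1 / (1 + (vc / v)^(2 * ord))
    m[!is.finite(m)] <- 0           # w = 0
    m
  }
  bandMag2 <- function(b, ord) {
    v1 <- tan(pi * b[1] / fs); v2 <- tan(pi * b[2] / fs)
    ratio <- (v^2 - v1 * v2) / (v * (v2 - v1))
    m <- 1 / (1 + ratio^(2 * ord))
    m[!is.finite(m)] <- 0           # w = 0 and w = pi
    m
  }
  if (band[1] / fs < 1e-3) {
    lowMag2(band[2], 4) * highMag2(band[1], 2)
  } else {
    bandMag2(band, 4)
  }
}

## Band-limited analytic signal through one FFT round trip: apply the
## zero-phase Butterworth magnitude response and the analytic-signal step in
## the frequency domain. X = fft(samples) may be precomputed and shared
## across bands. Equivalent to bandpass + Hilbert away from the wraparound
## margins, which callers exclude via edgeSamples.
.analyticBand <- function(trace, band, X = NULL) {
  x <- trace@samples
  n <- length(x)
  if (is.null(X)) X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  mag2 <- .bandMag2(band, trace@samplingRate, n)
  stats::fft(X * mag2 * h, inverse = TRUE) / n
}

#' Instantaneous phase of a frequency band
#'
#' Band-limits the trace with the zero-phase Butterworth magnitude response
#' (applied spectrally, fused with the Hilbert transform in one FFT round
#' trip) and takes the angle of the analytic signal. Phase 0 falls at the positive peak
#' of the band-passed oscillation and advances at `2*pi*f` rad/s for an
#' in-band sinusoid. One period of the band's lower edge at each end of the
#' series is flagged as edge-contaminated (`edgeSamples`) and is excluded
#' from spike-phase lookup by downstream consumers.
#'
#' @param trace a [Trace-class], already at the analysis rate (decimate
#'   first; see [decimateTo()]).
#' @param band `c(fLo, fHi)` band in Hz.
#' @return A [PhaseSeries-class].
#' @examples
#' t <- seq(0, 10, by = 1e-3)[-1]
#' ph <- hilbertPhase(Trace(cos(2 * pi * 10 * t), 1000, "uV", "lfp"), c(4, 20))
#' @export
hilbertPhase <- function(trace, band) {
  stopifnot(is(trace, "Trace"))
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be c(fLo, fHi) with 0 < fLo < fHi", call. = FALSE)
  .checkCutoff(band, trace@samplingRate)
  ph <- Arg(.analyticBand(trace, band))
  ## the FFT round trip is circular: exclude a few periods of the band's
  ## lower edge at each end, where wraparound contaminates the phase
  edge <- as.integer(ceiling(3 * trace@samplingRate / band[1]))
  new("PhaseSeries", phases = ph, samplingRate = trace@samplingRate,
      t0 = trace@t0, band = as.numeric(band),
      edgeSamples = min(edge, length(ph) %/% 2L))
}
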