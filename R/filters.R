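#' @include AllClasses.R
NULL

## Zero-phase IIR filtering. Filter designs come from signal::butter; the
## forward-backward pass itself runs through a compiled direct-form-II
## transposed kernel with odd-reflection padding and steady-state initial
## conditions, so that step inputs produce no start-up transient.

.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  M <- diag(n - 1) - t(comp)
  rhs <- b[2:n] - a[2:n] * b[1]
  zi <- try(solve(M, rhs), silent = TRUE)
  if (inherits(zi, "try-error"))   # near-singular for very low cutoffs
    zi <- qr.coef(qr(M, LAPACK = TRUE), rhs)
  zi[!is.finite(zi)] <- 0
  zi
}

.filtfilt <- function(b, a, x, padlen = NULL) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(x)
  if (is.null(padlen))
    padlen <- 3 * (max(length(a), length(b)) - 1) * 10
  padlen <- min(n - 1, padlen)
  if (padlen < 1) stop("signal too short to filter", call. = FALSE)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- .lfilterZi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

.checkCutoff <- function(fc, rate) {
  nyq <- rate / 2
  if (any(fc <= 0) || any(fc >= nyq))
    stop(sprintf("cutoff frequency must lie in (0, %g) Hz (Nyquist)", nyq),
         call. = FALSE)
}

## padHz: lowest characteristic frequency of the filter; padding spans a few
## of its periods so edge transients decay inside the pad
.applyFilter <- function(trace, b, a, padHz = NULL) {
  padlen <- if (is.null(padHz)) NULL
            else as.integer(ceiling(3 * trace@samplingRate / padHz))
  new("Trace", samples = .filtfilt(b, a, trace@samples, padlen = padlen),
      samplingRate = trace@samplingRate, units = trace@units,
      kind = trace@kind, t0 = trace@t0)
}

#' Zero-phase Butterworth filtering
#'
#' 4th-order Butterworth filters applied forward and backward (zero phase),
#' the standard choice for field-potential work because it preserves
#' spike/LFP timing relationships. `highpass()` removes DC;
#' all three return a trace of unchanged length and metadata.
#'
#' @param trace a [Trace-class].
#' @param fLo,fHi band edges in Hz (bandpass), `0 < fLo < fHi < Nyquist`.
#' @param fC cutoff frequency in Hz (lowpass/highpass).
#' @param order filter order (default 4).
#' @return A filtered [Trace-class].
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' tr <- Trace(sin(2 * pi * 40 * t), 1000, "uV", "lfp")
#' bp <- bandpass(tr, 20, 60)   # in-band: amplitude preserved
#' @export
bandpass <- function(trace, fLo, fHi, order = 4) {
  stopifnot(is(trace, "Trace"))
  if (fLo >= fHi) stop("fLo must be below fHi", call. = FALSE)
  .checkCutoff(c(fLo, fHi), trace@samplingRate)
  bf <- signal::butter(order, c(fLo, fHi) / (trace@samplingRate / 2),
                       type = "pass")
  .applyFilter(trace, bf$b, bf$a, padHz = fLo)
}

#' @rdname bandpass
#' @export
lowpass <- function(trace, fC, order = 4) {
  stopifnot(is(trace, "Trace"))
  .checkCutoff(fC, trace@samplingRate)
  bf <- signal::butter(order, fC / (trace@samplingRate / 2), type = "low")
  .applyFilter(trace, bf$b, bf$a, padHz = fC)
}

#' @rdname bandpass
#' @export
highpass <- function(trace, fC, order = 4) {
  stopifnot(is(trace, "Trace"))
  .checkCutoff(fC, trace@samplingRate)
  bf <- signal::butter(order, fC / (trace@samplingRate / 2), type = "high")
  .applyFilter(trace, bf$b, bf$a, padHz = fC)
}

#' Anti-aliased decimation to a target rate
#'
#' Low-pass filters with a zero-phase FIR anti-alias filter (windowed-sinc,
#' cutoff at the target Nyquist) and keeps every q-th sample, where
#' `q = samplingRate / targetRate` must be an integer. Naive subsampling is
#' never performed.
#'
#' @param trace a [Trace-class].
#' @param targetRate target sampling rate in Hz.
#' @return A [Trace-class] at `targetRate`.
#' @examples
#' tr <- Trace(rnorm(20000), 20000, "uV", "lfp")
#' lowRate <- decimateTo(tr, 1000)   # length 1000
#' @export
decimateTo <- function(trace, targetRate) {
  stopifnot(is(trace, "Trace"))
  .assertScalar(targetRate, "targetRate")
  if (targetRate > trace@samplingRate)
    stop("targetRate exceeds the trace sampling rate", call. = FALSE)
  if (targetRate == trace@samplingRate) return(trace)
  q <- trace@samplingRate / targetRate
  if (abs(q - round(q)) > 1e-9)
    stop("samplingRate must be an integer multiple of targetRate",
         call. = FALSE)
  q <- as.integer(round(q))
  ntaps <- 20L * q
  ## cutoff at 90% of the target Nyquist: the windowed-sinc transition band
  ## then finishes below the new Nyquist instead of straddling it
  h <- signal::fir1(ntaps, 0.9 / q)        # linear-phase, ntaps + 1 long
  x <- trace@samples
  n <- length(x)
  half <- ntaps %/% 2L
  pad <- pmin(half, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  y <- as.numeric(y)[(pad + 1):(pad + n)]
  new("Trace", samples = y[seq(1, n, by = q)], samplingRate = targetRate,
      units = trace@units, kind = trace@kind, t0 = trace@t0)
}
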