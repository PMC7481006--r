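#' @include AllClasses.R
NULL

## Unitary synaptic train analysis. Conventions:
##  - failures are decided per trial: the trial amplitude (read at the
##    mean-trace peak latency, averaged over +/- 0.5 ms, relative to the
##    trial's pre-pulse baseline) below failure_k x baseline noise SD; the
##    response-peak latency is located on the mean trace within a 2-18 ms
##    post-stimulus window (a raw per-trial max over that window would
##    exceed 3 sd by chance alone in a fifth of pure-noise trials);
##  - amplitudes, rise time and decay tau come from the mean trace;
##  - later pulses are measured against the extrapolated exponential decay
##    of the preceding response, which absorbs temporal summation;
##  - charge is the rectified integral of the baseline-subtracted mean trace
##    over [first stimulus, last stimulus + chargeTailMs].

.sweepMatrix <- function(rec) {
  ns <- vapply(rec@sweeps, function(tr) length(tr@samples), integer(1))
  if (length(unique(ns)) != 1)
    stop("sweeps must share one length", call. = FALSE)
  do.call(rbind, lapply(rec@sweeps, function(tr) tr@samples))
}

.pulsePeak <- function(x, fs, stim, respWin, sign) {
  i1 <- .sampleIndex(stim + respWin[1] / 1000, fs)
  i2 <- .sampleIndex(stim + respWin[2] / 1000, fs)
  base <- mean(x[.sampleIndex(stim - 0.002, fs):(.sampleIndex(stim, fs) - 1L)])
  list(peak = max(sign * (x[i1:i2] - base)), base = base,
      peakIdx = i1 - 1L + which.max(sign * (x[i1:i2] - base)))
}

#' Analyze a unitary synaptic train recording
#'
#' Computes per-pulse amplitudes, failure rates, total train charge, first
#' response kinetics (20-80% rise time, single-exponential decay of the last
#' response) and short-term plasticity ratios from a set of aligned
#' postsynaptic current sweeps evoked by a 5-pulse presynaptic train.
#'
#' Sweeps that clip (runs of samples pinned at the recorded extreme) are
#' excluded with a warning. If every trial of the first pulse is a failure,
#' the first-pulse amplitude is reported as `NA` and the failure rate as 1.
#'
#' @param rec a [PairedTrainRecording-class] (>= 10 sweeps).
#' @param failureK failure criterion: a trial response is a failure when its
#'   peak is below `failureK` times the baseline noise SD.
#' @param respWindowMs post-stimulus search window for the response peak
#'   (ms), default 2-18 ms.
#' @param chargeTailMs integration tail after the last stimulus (ms).
#' @return A [TrainResponseStats-class].
#' @export
analyzeTrain <- function(rec, failureK = 3, respWindowMs = c(2, 18),
                         chargeTailMs = 200) {
  stopifnot(is(rec, "PairedTrainRecording"))
  if (length(rec@sweeps) < 10)
    stop("at least 10 sweeps are required", call. = FALSE)
  fs <- rec@sweeps[[1]]@samplingRate
  X <- .sweepMatrix(rec)
  ## clipped-sweep exclusion: >= 5 consecutive samples at the global extreme
  clipped <- apply(X, 1, function(x) {
    ex <- max(abs(x))
    r <- rle(abs(x) >= ex * (1 - 1e-12))
    ex > 0 && any(r$lengths[r$values] >= 5)
  })
  if (any(clipped)) {
    warning(sprintf("excluding %d clipped sweep(s)", sum(clipped)))
    X <- X[!clipped, , drop = FALSE]
    if (nrow(X) < 10)
      stop("fewer than 10 usable sweeps after clipping exclusion",
           call. = FALSE)
  }
  s <- if (rec@polarity == "inward") -1 else 1
  st <- rec@stimTimes
  nP <- length(st)
  bIdx <- .sampleIndex(rec@baselineWindow[1], fs):
          (.sampleIndex(rec@baselineWindow[2], fs) - 1L)
  noiseSd <- apply(X[, bIdx, drop = FALSE], 1, stats::sd)
  ## mean-trace measures; for pulses after the first, the pre-pulse
  ## baseline is the extrapolated exponential decay of the preceding
  ## response (temporal summation correction), not a constant
  M <- colMeans(X)
  base0 <- mean(M[bIdx])
  amp <- numeric(nP); peakIdx <- integer(nP); localBase <- numeric(nP)
  for (k in seq_len(nP)) {
    pp <- .pulsePeak(M, fs, st[k], respWindowMs, s)
    peakIdx[k] <- pp$peakIdx; localBase[k] <- pp$base
    if (k == 1) {
      amp[k] <- pp$peak
    } else {
      i1 <- .sampleIndex(st[k] + respWindowMs[1] / 1000, fs)
      i2 <- .sampleIndex(st[k] + respWindowMs[2] / 1000, fs)
      j1 <- .sampleIndex(st[k] - 0.005, fs); j2 <- .sampleIndex(st[k], fs) - 1L
      yb <- s * (M[j1:j2] - base0)
      ttb <- (seq_along(yb) - 1) / fs
      pred <- rep(mean(yb), i2 - i1 + 1L)
      if (all(yb > 0)) {
        efit <- try(minpack.lm::nlsLM(
          yb ~ a * exp(-ttb / tau),
          start = list(a = max(yb[1], 1e-6), tau = 0.015),
          lower = c(0, 1e-4),
          control = minpack.lm::nls.lm.control(maxiter = 100)),
          silent = TRUE)
        if (!inherits(efit, "try-error")) {
          cf <- stats::coef(efit)
          tpred <- ((i1:i2) - j1) / fs
          pred <- cf["a"] * exp(-tpred / cf["tau"])
        }
      }
      amp[k] <- max(s * (M[i1:i2] - base0) - pred)
    }
  }
  ## trial-level amplitudes at the mean-trace peak latency
  halfw <- max(1L, as.integer(round(0.0005 * fs)))
  trialAmp <- matrix(0, nrow(X), nP)
  for (k in seq_len(nP)) {
    win <- max(1L, peakIdx[k] - halfw):min(ncol(X), peakIdx[k] + halfw)
    bwin <- (.sampleIndex(st[k] - 0.002, fs)):(.sampleIndex(st[k], fs) - 1L)
    trialAmp[, k] <- s * (rowMeans(X[, win, drop = FALSE]) -
                          rowMeans(X[, bwin, drop = FALSE]))
  }
  failures <- trialAmp < failureK * noiseSd
  failureRate <- colMeans(failures)
  ampSuccesses <- vapply(seq_len(nP), function(k) {
    ok <- !failures[, k]
    if (!any(ok)) NA_real_ else mean(trialAmp[ok, k])
  }, numeric(1))
  if (failureRate[1] >= 1) amp[1] <- NA_real_
  ## charge: rectified toward the response polarity, pA * s = pC
  qi1 <- .sampleIndex(st[1], fs)
  qi2 <- min(length(M), .sampleIndex(st[nP] + chargeTailMs / 1000, fs))
  q <- sum(pmax(s * (M[qi1:qi2] - base0), 0)) / fs
  ## rise time (20-80% of the first-pulse mean response)
  riseTime <- NA_real_
  if (!is.na(amp[1]) && amp[1] > 0) {
    seg <- s * (M[.sampleIndex(st[1], fs):peakIdx[1]] - localBase[1])
    t20 <- .firstCrossingUp(seg, 0.2 * amp[1], 1 / fs)
    t80 <- .firstCrossingUp(seg, 0.8 * amp[1], 1 / fs)
    if (!is.na(t20) && !is.na(t80)) riseTime <- (t80 - t20) * 1000
  }
  ## decay tau: single exponential from 90% of the last-pulse peak; the
  ## tail decays toward the global baseline (all pulse tails share tau)
  decayTau <- NA_real_
  if (amp[nP] > 0) {
    segIdx <- peakIdx[nP]:qi2
    y <- s * (M[segIdx] - base0)
    startOff <- .firstCrossingDown(y, 0.9 * y[1], 1)
    i0 <- if (is.na(startOff)) 1L else as.integer(ceiling(startOff)) + 1L
    y <- y[i0:length(y)]
    tt <- (seq_along(y) - 1) / fs
    a0 <- y[1]
    blw <- which(y < a0 / exp(1))
    tau0 <- if (length(blw)) max(tt[blw[1]], 2 / fs) else max(tt) / 3
    fit <- try(minpack.lm::nlsLM(
      y ~ a * exp(-tt / tau), start = list(a = a0, tau = tau0),
      lower = c(0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error"))
      decayTau <- unname(stats::coef(fit)["tau"]) * 1000
  }
  stp <- if (is.na(amp[1]) || amp[1] == 0) rep(NA_real_, nP) else amp / amp[1]
  new("TrainResponseStats", amp = amp, ampSuccesses = ampSuccesses,
      failureRate = failureRate, q = q, riseTime = riseTime,
      decayTau = decayTau, stpRatio = stp, nSweeps = nrow(X))
}

#' Short-term plasticity profile
#'
#' Normalizes the per-pulse amplitudes of a train to the first pulse and
#' classifies the train as depressing (mean of the later ratios below 1) or
#' facilitating (above 1).
#'
#' @param stats a [TrainResponseStats-class] with a defined first-pulse
#'   amplitude.
#' @return A list with `ratios` (numeric, `ratios[1] == 1`) and
#'   `classification` (`"depressing"`, `"facilitating"` or `"neutral"`).
#' @export
stpProfile <- function(stats) {
  stopifnot(is(stats, "TrainResponseStats"))
  if (is.na(stats@amp[1]) || stats@amp[1] == 0)
    stop("first-pulse amplitude undefined; STP profile unavailable",
         call. = FALSE)
  ratios <- stats@amp / stats@amp[1]
  m <- mean(ratios[-1])
  cls <- if (m < 1) "depressing" else if (m > 1) "facilitating" else "neutral"
  list(ratios = ratios, classification = cls)
}

#' Pharmacological block fraction
#'
#' Percentage block of the first-pulse amplitude by a drug condition:
#' `100 * (1 - amp_drug / amp_ctrl)`.
#'
#' @param ctrl,drug [TrainResponseStats-class] for the control and drug
#'   condition of the same pair.
#' @return Percent block (numeric scalar).
#' @examples
#' ## a 100 pA control response reduced to 59 pA is a 41% block
#' @export
blockFraction <- function(ctrl, drug) {
  stopifnot(is(ctrl, "TrainResponseStats"), is(drug, "TrainResponseStats"))
  a0 <- ctrl@amp[1]; a1 <- drug@amp[1]
  if (is.na(a0) || a0 <= 0)
    stop("control amplitude must be positive", call. = FALSE)
  100 * (1 - a1 / a0)
}
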