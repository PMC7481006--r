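#' @include AllClasses.R
NULL

#' UP/DOWN state evidence variable
#'
#' Builds the combined state-evidence series from a decimated LFP: the sum
#' of (i) the z-scored log power of the high-frequency band (envelope power
#' of the band-passed analytic signal, smoothed over `powerWindowMs`) and
#' (ii) the z-scored cosine of the slow-oscillation phase relative to the
#' reference phase at which high-frequency power is maximal (estimated from
#' the data as the power-weighted circular mean of the slow phase). Because
#' both terms are z-scored over the recording, the evidence is invariant to
#' affine transforms of the LFP.
#'
#' @param lfp an LFP [Trace-class] at the analysis rate (>= 10 s).
#' @param slowBand slow-oscillation band (Hz), default 0.1-4 Hz.
#' @param hfBand high-frequency band (Hz), default 20-100 Hz.
#' @param powerWindowMs power smoothing window (ms).
#' @return A [StateEvidence-class].
#' @seealso [detectStates()]
#' @export
stateEvidence <- function(lfp, slowBand = c(0.1, 4), hfBand = c(20, 100),
                          powerWindowMs = 100) {
  stopifnot(is(lfp, "Trace"))
  if (duration(lfp) < 10)
    stop("recording shorter than 10 s: too short for mixture fitting",
         call. = FALSE)
  fs <- lfp@samplingRate
  hf <- bandpass(lfp, hfBand[1], hfBand[2])
  pow <- Mod(.analytic(hf@samples))^2
  pow <- .movavg(pow, as.integer(round(powerWindowMs / 1000 * fs)))
  logPow <- log(pow + 1e-12 * max(pow, 1e-300))
  zHf <- .zscore(logPow)
  slowPh <- hilbertPhase(lfp, slowBand)@phases
  phiRef <- Arg(sum(pow * exp(1i * slowPh)))
  zSlow <- .zscore(cos(slowPh - phiRef))
  new("StateEvidence", sComb = zHf + zSlow, samplingRate = fs, t0 = lfp@t0,
      slowPhaseTerm = zSlow, highFreqTerm = zHf, window = powerWindowMs)
}

## Order mixture components by mean, refuse degenerate (collapsed) fits and
## derive the UP/DOWN classification thresholds.
.makeGMMFit <- function(mu, sg, wt, thresholdSds = 3, downSide = +1) {
  ord <- base::order(mu)
  mu <- mu[ord]; sg <- sg[ord]; wt <- wt[ord]
  sep <- diff(mu)
  sgMax <- pmax(sg[-3], sg[-1])
  if (any(sep < 0.1 * sgMax))
    stop(sprintf(paste0("degenerate mixture: component means %.3f/%.3f/%.3f ",
                        "are not separated (< 0.1 sd); segmentation refused"),
                 mu[1], mu[2], mu[3]), call. = FALSE)
  new("GMMFit", means = unname(mu), sds = unname(sg), weights = unname(wt),
      thUp = mu[3] - thresholdSds * sg[3],
      thDown = mu[1] + sign(downSide) * thresholdSds * sg[1])
}

## Runs of a logical vector as (start, end) sample indices (inclusive).
.runsOf <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect UP/DOWN cortical states from the evidence variable
#'
#' Fits the evidence distribution with a mixture of three Gaussians (one per
#' cortical state; components labeled DOWN, INTERMEDIATE, UP by ascending
#' mean), classifies samples against the thresholds
#' `thUp = mu_UP - k sd_UP` and `thDown = mu_DOWN + k sd_DOWN` (k = 3), and
#' refines the labeling with two constraints: same-label intervals separated
#' by less than `minIntervalMs` are merged, and UP/DOWN intervals shorter
#' than `minDurationMs` are relabeled INTERMEDIATE. By default merging runs
#' before the duration filter; the order is configurable.
#'
#' The DOWN threshold uses `mu_DOWN + k sd_DOWN` (above the DOWN mean):
#' thresholds symmetric about the component means select the intended
#' extreme tails on both sides. The sidedness is configurable via
#' `downSide`.
#'
#' @param evidence a [StateEvidence-class] over at least 10 s.
#' @param minIntervalMs minimum interval between two same-label states (ms).
#' @param minDurationMs minimum UP/DOWN state duration (ms).
#' @param thresholdSds the threshold multiplier k.
#' @param downSide `+1` places the DOWN threshold at `mu_DOWN + k sd_DOWN`
#'   (default); `-1` reproduces the subtractive form.
#' @param order `"merge_first"` (default) or `"filter_first"`.
#' @param maxFitSamples evidence samples used for mixture fitting (an even
#'   deterministic subsample keeps the fit fast on long recordings).
#' @param seed optional integer seed (the mixture fit is deterministic
#'   either way; the seed guards any future stochastic initialisation).
#' @return A list with elements `gmm` ([GMMFit-class]) and `segmentation`
#'   ([StateSegmentation-class]).
#' @export
detectStates <- function(evidence, minIntervalMs = 50, minDurationMs = 70,
                         thresholdSds = 3, downSide = +1,
                         order = c("merge_first", "filter_first"),
                         maxFitSamples = 20000, seed = NULL) {
  stopifnot(is(evidence, "StateEvidence"))
  order <- match.arg(order)
  s <- evidence@sComb
  fs <- evidence@samplingRate
  if (length(s) / fs < 10)
    stop("evidence shorter than 10 s", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sub <- s[unique(as.integer(round(seq(1, length(s),
                                       length.out = min(maxFitSamples,
                                                        length(s))))))]
  fit <- mclust::Mclust(sub, G = 3, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    stop("Gaussian mixture fit failed on the evidence distribution",
         call. = FALSE)
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 3)
  gmm <- .makeGMMFit(mu, sg, fit$parameters$pro, thresholdSds, downSide)
  mu <- gmm@means
  thUp <- gmm@thUp; thDown <- gmm@thDown
  lab <- rep("INTERMEDIATE", length(s))
  lab[s > thUp] <- "UP"
  lab[lab != "UP" & s < thDown] <- "DOWN"
  if (thUp < thDown) {
    ## widely spread components make the 3 sd thresholds cross; samples
    ## claimed by both sides go to the nearer extreme component
    amb <- s > thUp & s < thDown
    mid <- (mu[1] + mu[3]) / 2
    lab[amb] <- ifelse(s[amb] >= mid, "UP", "DOWN")
  }
  gapSamp <- minIntervalMs / 1000 * fs
  durSamp <- minDurationMs / 1000 * fs
  mergeStep <- function(lab) {
    for (L in c("UP", "DOWN")) {
      other <- setdiff(c("UP", "DOWN"), L)
      runs <- .runsOf(lab == L)
      if (nrow(runs) < 2) next
      for (i in seq_len(nrow(runs) - 1)) {
        gap <- (runs[i, "end"] + 1L):(runs[i + 1, "start"] - 1L)
        if (length(gap) < gapSamp && !any(lab[gap] == other))
          lab[gap] <- L
      }
    }
    lab
  }
  filterStep <- function(lab) {
    for (L in c("UP", "DOWN")) {
      runs <- .runsOf(lab == L)
      if (!nrow(runs)) next
      short <- (runs[, "end"] - runs[, "start"] + 1L) < durSamp
      for (i in which(short))
        lab[runs[i, "start"]:runs[i, "end"]] <- "INTERMEDIATE"
    }
    lab
  }
  ## iterate the two refinement rules to a fixed point: a single pass can
  ## leave same-label intervals separated by a sub-minInterval gap (a short
  ## opposite-state dip blocks the merge until the duration rule relabels
  ## it), and the declared segmentation invariants require both constraints
  ## to hold simultaneously
  for (it in 1:10) {
    prev <- lab
    lab <- if (order == "merge_first") filterStep(mergeStep(lab))
           else mergeStep(filterStep(lab))
    if (identical(lab, prev)) break
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = evidence@t0 + (starts - 1L) / fs,
                   end = evidence@t0 + ends / fs,
                   label = r$values, stringsAsFactors = FALSE)
  seg <- new("StateSegmentation", intervals = iv,
             minInterval = minIntervalMs, minDuration = minDurationMs,
             recordDuration = length(s) / fs)
  list(gmm = gmm, segmentation = seg)
}

#' Per-state summary statistics
#'
#' For each state label: how often the state occurs (states per minute of
#' recording), its mean duration (ms), and the spiking rate inside it
#' (spikes within the label's intervals divided by the label's total time).
#' A label absent from the segmentation yields `NA` statistics (flagged by
#' `present = FALSE`), not zeros.
#'
#' @param seg a [StateSegmentation-class].
#' @param spikes a [SpikeTrain-class] on the same time base.
#' @return data.frame with columns `label`, `present`, `frequencyPerMin`,
#'   `meanDurationMs`, `spikeRateHz`.
#' @export
stateStats <- function(seg, spikes) {
  stopifnot(is(seg, "StateSegmentation"), is(spikes, "SpikeTrain"))
  iv <- seg@intervals
  st <- spikeTimes(spikes)
  totMin <- seg@recordDuration / 60
  res <- lapply(c("UP", "DOWN", "INTERMEDIATE"), function(L) {
    sel <- iv[iv$label == L, , drop = FALSE]
    if (!nrow(sel))
      return(data.frame(label = L, present = FALSE,
                        frequencyPerMin = NA_real_,
                        meanDurationMs = NA_real_, spikeRateHz = NA_real_))
    lens <- sel$end - sel$start
    nIn <- sum(vapply(seq_len(nrow(sel)), function(i)
      sum(st >= sel$start[i] & st < sel$end[i]), numeric(1)))
    data.frame(label = L, present = TRUE,
               frequencyPerMin = nrow(sel) / totMin,
               meanDurationMs = mean(lens) * 1000,
               spikeRateHz = nIn / sum(lens))
  })
  do.call(rbind, res)
}
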