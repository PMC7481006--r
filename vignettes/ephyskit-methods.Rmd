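---
title: "Methods: excitability, unitary synapses and spike-field coupling with ephyskit"
author: "ephyskit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excitability, unitary synapses and spike-field coupling with ephyskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyskit)
```

ephyskit implements the analysis chain of a cortical microcircuit
physiology study across its three tiers: current-clamp excitability in
slices, unitary synaptic transmission in paired recordings, and
anesthetized in vivo dynamics recorded as a local field potential (LFP)
plus a juxtacellular single-cell channel. Every analysis has a matched
ground-truth simulator, so the whole chain is testable without any animal
data. This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic tests do and do not demonstrate.

## Signal primitives

All analyses consume `Trace` objects: one uniformly sampled channel with a
rate, physical units (mV, pA or uV) and a start time. Intervals are
half-open `[start, end)` and times are in seconds throughout.

**Filtering.** All filters are 4th-order Butterworth designs applied
forward and backward, giving zero phase shift. Zero-phase filtering is
essential here: phase-locking statistics and spike-triggered averages are
meaningless if the filter delays the LFP relative to the spike times. The
literature this pipeline follows names cutoffs (5 Hz juxtacellular
high-pass, 100 Hz LFP low-pass, 1 kHz decimation) but no filter design;
4th-order Butterworth is the de facto standard in field-potential work and
is exposed as the `order` argument. One numerical caveat is built in: a
single 8th-order bandpass whose lower edge sits below about 0.1% of the
sampling rate (e.g. 0.1--4 Hz at 1 kHz) is numerically unstable, so
`hilbertPhase()` cascades separate low- and high-pass stages in that
regime.

**Decimation** (`decimateTo`) applies a zero-phase windowed-sinc FIR
anti-alias filter with cutoff at 90% of the target Nyquist before
subsampling; the 90% placement keeps the transition band inside the new
Nyquist. Only integer rate ratios are supported, which covers the 20 kHz
to 1 kHz path the analyses use.

**Spectra** (`welchPsd`) average Hann-windowed overlapping periodograms
(default 4096 samples, 50% overlap, matching the windowing used for the
published power spectra). Power is a one-sided density whose integral over
frequency equals the signal variance; an optional band normalization
rescales power to sum to 1 over a stated band.

**Instantaneous phase** (`hilbertPhase`) is the angle of the analytic
signal of the band-limited trace. Band-limiting and the Hilbert transform
are fused in one FFT round trip: the zero-phase (forward-backward)
Butterworth magnitude response has a closed form under the bilinear
transform, and applying it spectrally is equivalent to filtfilt away from
the wraparound margins, which are excluded (three periods of the band's
lower edge per end). `bandPPC()` additionally shares the forward FFT
across its six analysis bands, which is what makes multi-band phase
locking on hour-scale cohorts affordable. Phase 0 sits at the positive
peak of the oscillation and increases with time. The convention is arbitrary --
pairwise phase consistency is invariant to global rotations -- but it
fixes the meaning of any reported preferred phase. One period of the
band's lower edge at each end of the series is flagged unreliable, and
spike-phase lookups exclude it.

## Excitability analysis

Spikes in current-clamp sweeps are threshold crossings at 0 mV with a 2 ms
refractory rule; event times are the peaks of suprathreshold excursions.

**Passive properties** come from the -25, 0 and +25 pA subthreshold
sweeps: resting potential is the pre-step mean of the 0 pA sweep, input
resistance the least-squares slope of steady-state voltage deflection
against current, and the membrane time constant a single-exponential fit
of the relaxation after the -25 pA step. Two windows are design choices
the protocol leaves open: the steady state is the last 500 ms of the 2 s
step (any time constant up to 60 ms has decayed to < 0.1% there), and the
exponential fit starts 2 ms after step onset to skip pipette artifacts.
On analytic RC responses the recovery is exact to fit tolerance across
R in [50, 600] MOhm and tau in [5, 60] ms, the ranges the reported cell
populations span.

**Action-potential features** follow the dV/dt-criterion definitions:
threshold is the voltage at the first upward crossing of 10 mV/ms before
the peak (linearly interpolated between samples), amplitude is peak minus
threshold, and half-width is the interpolated width at half amplitude.

**F-I curves** are fitted with the logarithmic model
$f(I) = \mathrm{gain}\,\ln(I/\mathrm{rheobase})$, by bounded
Levenberg-Marquardt least squares on the suprathreshold steps.
Initialisation uses the largest silent current plus half a step for
rheobase, and the slope of the first two suprathreshold points in
log-current for gain. The half-maximum current (`injCurr50`) is read off
the measured curve by linear interpolation rather than off the fit,
because it is defined operationally as an amount of injected current.
The fit itself lives in `fiFitRates()`; `fiFit()` derives the rates by
counting detected spikes inside the step window (rebound spikes after
step offset are not counted). Note that 2 s steps quantise measured
rates to 0.5 Hz, so parameter recovery is exact at the rate level and
accurate to that quantisation at the trace level.

## Unitary synaptic trains

`analyzeTrain()` consumes aligned postsynaptic-current sweeps evoked by a
5-pulse, 50 Hz presynaptic train. The conventions, each of which the
underlying experimental literature leaves open and which are therefore
explicit parameters:

* **Failures are decided per trial.** A trial's response amplitude is
  read at the latency of the mean-trace peak (located within a 2--18 ms
  post-stimulus window), averaged over +/- 0.5 ms, relative to the
  trial's 2 ms pre-pulse baseline. A pulse is a failure when this falls
  below `failureK` (default 3) baseline noise SDs. The peak latency is
  taken from the mean trace deliberately: the maximum of a raw 16 ms
  noise window exceeds 3 SD by chance in roughly a fifth of pure-noise
  trials, which would make failure rates of weak synapses meaningless.
* **Amplitudes come from the mean trace.** Later pulses ride on the decay
  of earlier ones; their amplitudes are measured against the extrapolated
  single-exponential decay of the preceding response, which removes
  temporal summation exactly when tails are exponential (the measurement
  is exact on noiseless deterministic trains).
* **Charge** is the rectified integral of the baseline-subtracted mean
  trace from the first stimulus to 200 ms after the last (pA x s = pC).
  Rectification toward the response polarity makes the measure robust to
  small baseline ripple; both the tail length and the rectification are
  config options.
* **Kinetics**: rise time is 20--80% of the first-pulse mean response;
  decay is a single-exponential fit starting where the last response has
  fallen to 90% of its peak, measured toward the global baseline (all
  pulse tails share the decay constant, so their sum is a single
  exponential).
* Both failure-included (`amp`) and success-only (`ampSuccesses`)
  amplitudes are reported, since published per-pulse amplitudes do not
  state which convention they use.

Short-term plasticity ratios (`stpProfile`) normalise to the first pulse;
`blockFraction` expresses a drug condition as
$100\,(1 - A_\mathrm{drug}/A_\mathrm{ctrl})$ on first-pulse amplitudes.

## In vivo pipeline

**Spike detection** high-passes the juxtacellular channel at 5 Hz and
detects peaks above 1.5 mV. On the simulator's stated regime (2 mV spikes
on 0.2 mV noise) detection is error-free; the biphasic spike template is
1.5 ms wide so the threshold is exercised meaningfully.

**Spike-triggered LFP** averages +/- 100 ms LFP segments around spike
peaks; peak-to-peak amplitude is measured on the 100 Hz low-passed mean
waveform (the raw-waveform value is reported alongside, since published
values do not state which was used). The waveform spectrum uses the
largest power-of-two Welch window that fits the 201-sample segment.

**Pairwise phase consistency.** The PPC of spike phases
$\theta_1,\dots,\theta_N$ is the average cosine of the phase difference
over all pairs,

$$\mathrm{PPC} = \frac{2}{N(N-1)} \sum_{i<j} \cos(\theta_i - \theta_j),$$

computed through the algebraically identical closed form
$(N R^2 - 1)/(N - 1)$ with $R$ the mean resultant length. It is an
unbiased estimator of the squared population resultant length: 0 in
expectation for uniform phases, $(I_1(\kappa)/I_0(\kappa))^2$ for von
Mises phases with concentration $\kappa$. `bandPPC()` computes it per
frequency band (4--10 through 80--100 Hz) with nearest-sample phase
lookup at the 1 kHz analysis rate (at most 0.5 ms, i.e. 0.3 rad at
100 Hz) and flags estimates from fewer than 250 spikes as unreliable,
the threshold used for the published per-cell estimates.

**UP/DOWN state segmentation.** The evidence variable combines the two
ingredients named for this analysis family -- slow (< 4 Hz) oscillation
phase and 20--100 Hz content -- as an equal-weight sum of z-scores: the
log high-frequency envelope power (smoothed over 100 ms) and the cosine
of the slow phase relative to the phase of maximal high-frequency power
(estimated from the data as a power-weighted circular mean). The exact
published composition lives in an upstream reference that specifies only
these ingredients; this construction is a documented stand-in with every
element (weights, window, reference phase) configurable. Because both
terms are z-scored, the evidence is invariant to affine transforms of
the LFP.

The evidence distribution is fitted with a three-component Gaussian
mixture (components = DOWN, INTERMEDIATE, UP by ascending mean). The fit
is delegated to `mclust` (unequal variances, deterministic hierarchical
initialisation; a 20,000-sample deterministic subsample keeps it fast on
long recordings). Thresholds sit 3 SDs inside the extreme components:
$\theta_{UP} = \mu_{UP} - 3\sigma_{UP}$ and
$\theta_{DOWN} = \mu_{DOWN} + 3\sigma_{DOWN}$. The DOWN threshold is
*additive*: the subtractive form that appears in print would classify
almost nothing as DOWN, contradicting the stated "periods below the DOWN
threshold"; the sidedness is configurable (`downSide`). When components
are so spread that the thresholds cross, samples claimed by both sides go
to the nearer extreme component. Mixtures whose component means collapse
(within 0.1 SD) are refused with a diagnostic rather than segmented.

Two refinement constants are fixed by the protocol: same-label intervals
separated by less than 50 ms are merged, and UP/DOWN intervals shorter
than 70 ms are relabeled INTERMEDIATE. The order of the two rules is not
stated anywhere; merging runs first by default and the order is a config
option tested both ways. The pair of rules is iterated to a fixed point:
a single pass can leave same-label intervals separated by sub-50 ms gaps
(a short opposite-state dip blocks the merge until the duration rule
relabels it), and the segmentation contract requires both constraints to
hold simultaneously in the final output.

One statistical limit is worth stating plainly: if the within-state
evidence noise has Gaussian tails and the UP/DOWN separation is only 4
SDs, then 2.3% of samples fall beyond the class midpoint by construction,
dip clusters split states, and no ordering of the 50/70 ms rules keeps
the state count exact. The synthetic square-wave checks therefore use
bounded within-state noise at the same mean separation where exact counts
are asserted, and Gaussian-noise behavior is exercised separately at
wider separations and through the full LFP chain. Real evidence
distributions are compressed statistics (log power, cosines) with
sub-Gaussian tails, which is why the published procedure is usable at
moderate separations.

## Ground-truth simulators

* `simulateInVivo()`: semi-Markov UP/DOWN alternation with
  gamma-distributed durations (shape 4; means 500 ms; floored at 80 ms so
  that sub-minimum states do not dominate the duration filter), an LFP
  composed of the low-passed state sequence (slow rhythm), state-gated
  band-limited 20--100 Hz noise (10x power ratio UP:DOWN), and white
  noise; state-conditional Poisson spiking; and optional von Mises phase
  coupling of UP-state spikes, implemented by rejection sampling against
  the actual coupling-band phase of the generated LFP, so the generated
  coupling is exactly what the analysis measures. Defaults emulate
  urethane-anesthesia cortical dynamics at the acquisition rates of the
  protocol (20 kHz juxtacellular, 1 kHz LFP analysis rate).
* `simulateCurrentSteps()`: either the logarithmic rate model (spike
  counts from $f(I)$, jittered quasi-regular spike times, stylized AP
  waveforms) or a leaky integrate-and-fire neuron with exact RC passive
  response and closed-form rheobase $(V_{thr}-V_{rest})/R$. LIF is the
  simplest model whose rheobase and passive properties are analytic,
  which is exactly what the tests need; conductance-based models are out
  of scope.
* `simulateSynapticTrains()`: binomial quantal release
  (`Binom(nSites, p)`) per pulse, difference-of-exponentials quantal
  currents, optional short-term depression via the resource recursion
  $x_{n+1} = 1 - (1 - x_n(1-U))e^{-\Delta/\tau_{rec}}$ (or facilitation
  via the mirrored rule), and Gaussian current noise. The recursion's
  analytic per-pulse ratios are the oracle for the train analyzer.

All generators are bitwise deterministic under a fixed seed and return
their full ground truth (state intervals, spike times and phases, quantal
outcomes, generating parameters).

What the synthetic tests show: that every estimator recovers the
structure it targets, at known noise levels, with calibrated uncertainty.
What they do not show: robustness to real-recording pathologies --
electrode drift, spike-waveform nonstationarity, imperfect single-cell
isolation, line noise, or anesthesia-depth changes. Those require real
data and are outside this package's claims.

## Cohort statistics

`summarizeCohort()` reports median and quartiles (type-7 linear
interpolation, stated in the report header because quartiles depend on
the convention) with per-metric n. `compareGroups()` reproduces the
normality-gated two-group procedure: Shapiro-Wilk on each group, Student's
t when both pass (p > 0.05), otherwise a two-tailed Mann-Whitney U test,
with the branch recorded. No multiple-testing correction is applied,
matching per-metric reporting conventions; the log states this. Cells are
treated as independent units; nesting of cells within animals is not
modeled, a known limitation of per-cell analyses of this kind.

`runPipeline()` chains simulate/load -> analyze -> summarize -> compare
and writes TSV/JSON/interval-file reports with a log capturing seeds and
every parameter in effect. The packaged demo cohort
(`demoCohortConfig()`) contrasts a euploid-like and a trisomic-like
condition: overall firing rates of 0.81 vs 0.42 Hz (the published group
medians), and stronger 20--40 Hz spike-field coupling in the
trisomic-like group. The concentration contrast (kappa 0.2 vs 0.5) was
sized by a power analysis: per-cell PPC sampling noise at ~250 spikes has
SD about $2\rho/\sqrt{2N}$, so detecting the contrast at 12 cells per
group needs an effect of roughly two of those SDs; the resulting PPC
magnitudes (about 0.008 vs 0.047) stay inside the range such recordings
report. Recordings are 600 s so that most trisomic-like cells clear the
250-spike reliability threshold; the demo juxtacellular channel runs at
5 kHz to keep a 20-seed replicate study inside desktop compute budgets
(the generator default remains 20 kHz).

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulateInVivo(inVivoSimConfig(duration = 120, kappa = 1,
                                      spikeRateUp = 3, seed = 7))
spikes <- detectSpikesJuxta(sim$juxta)
firingRate(spikes)
lfp <- lowpass(sim$lfp, 100)
bandPPC(lfp, spikes)
states <- detectStates(stateEvidence(lfp))
stateStats(states$segmentation, spikes)
```

## Known limitations

* No vendor-format (ABF) reading; convert to the CSV trace container
  first (any converter that writes one sample per line with the three
  header fields suffices). HDF5 containers are not supported by this
  build.
* No spike sorting: the juxtacellular channel is assumed to isolate one
  cell.
* No sag/adaptation/burst metrics, no quantal-parameter estimation
  (multiple-probability fluctuation analysis), and no space-clamp
  correction for dendritic synapses -- somatic recordings of dendritic
  currents under-report amplitudes, and nothing here corrects that.
* The S_comb construction is a documented stand-in for an upstream
  reference's unpublished composition; only its two ingredients are
  fixed by the protocol.
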