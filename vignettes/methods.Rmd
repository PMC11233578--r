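---
title: "Models and methods in stimresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stimresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimresp)
```

`stimresp` implements the quantitative chain used to analyse
stimulus-evoked activity in cortical circuits at three levels: two-photon
calcium imaging of populations during repeated mechanical (von Frey)
stimulation, current-clamp characterisation of layer-1 interneurons, and
voltage-clamp isolation of feedforward inhibition. Because the motivating
data sets are not publicly deposited, every analysis is exercised against
forward-model simulators with planted ground truth; this vignette explains
the models, the tunable parameters, and the choices made where the methods
left the design open.

## Fluorescence normalisation: ΔF/F0

For each ROI $i$, normalised fluorescence around each stimulus is

$$\Delta F/F_0 \;=\; \frac{f_i - f_{b,i}}{f_{0,i}},$$

where $f_i$ is the extracted ROI fluorescence, $f_{b,i}$ is the mean of
$f_i$ over the 0.5 s preceding the stimulus onset (the event-local
baseline), and $f_{0,i}$ is the slow baseline: the 8th percentile of the
*sum* of the ROI fluorescence and the estimated background signal
overlapping the ROI, over a 1-s moving window. `running_percentile_baseline()`
computes $f_0$ with a centred window by default — a symmetric window avoids
phase lag in the baseline; a trailing window is available via
`percentile_centering = "trailing"` since the original description does not
fix the convention. Percentiles interpolate linearly between order
statistics (type 7), a convention chosen so that an independent
sort-and-index implementation reproduces the values exactly; the kernel is
implemented in C++ because it is evaluated once per frame per neuron.

Two practical consequences of this definition are worth knowing. First,
because $f_0$ is a *local* percentile, sustained transients are partially
divisively compressed (a +20% step normalises to $0.2/1.2 \approx 0.167$
at mid-plateau); analyses that compare evoked amplitudes across conditions
therefore always use the same windows. Second, a segment in which
$f_0 \le 0$ is not interpretable and is excluded with a report rather than
silently clamped.

Alignment windows default to 1 s before to 5 s after onset; frames are
assigned to half-open intervals $[t, t+\Delta)$ with the onset frame in the
post-window. Gaussian smoothing (`gaussian_smooth()`, default
$\sigma = 100$ ms) exists for display only and is never applied before
statistics.

## Evoked-response summaries

From the trial-mean trace the package computes signed trapezoidal areas
(AUC) over 0–5, 0–1 and 1–5 s and window means over 0–1 s (during the
stimulus) and 1–5 s (after it). Trapezoidal quadrature over closed
intervals was chosen so that areas over adjoining windows add exactly,
which the test-suite asserts on random traces. Session effects are
summarised as fold changes $( \mathrm{AUC}_{s} -
\mathrm{AUC}_{1}) / |\mathrm{AUC}_{1}|$; a zero reference makes the fold
change undefined, which is recorded as a flagged value, excluded from group
statistics and counted in QC, rather than an error. Layer assignment is an
interval lookup on the lens-referenced coordinate with half-open bins
(boundary coordinates belong to the deeper layer). The defaults (100 µm
and 350 µm cut points within a 900 µm range) are configuration standing in
for lens geometry, not measured anatomy, and should be overridden per
experiment.

## The circular-shift responsiveness bootstrap

A neuron is called responsive when its observed evoked statistic falls
outside the central 95% of a null distribution built by circularly
rotating its activity relative to the fixed stimulus times (1000 uniform
random shifts in $[1, T-1]$, drawn with replacement; shift 0 is excluded).
Rotation preserves the autocorrelation of the trace, which is what makes
this null appropriate for slow calcium signals.

The statistic is the mean ΔF/F0 over a configurable window (default 0–1 s
after onset) averaged across events, with the ΔF/F0 definition applied
*locally at every rotated position*: the pre-onset baseline $f_b$ is
recomputed on the rotated trace so the observed and null pipelines are
identical. Computationally the statistic decomposes into circular moving
means of $f/f_0$, $1/f_0$ and $f$, so the whole 1000-shift null costs
$O(T)$ plus table lookups per neuron. Subtracting the baseline in raw
fluorescence (rather than on an already-normalised trace) matters: the 1-s
percentile window tracks multi-second suppressions of activity, so a
purely $f_0$-relative statistic is nearly blind to inactivated neurons,
while the $f_b$-referenced statistic detects them reliably.

The comparison against the 2.5th/97.5th percentiles of the null is strict:
a degenerate constant trace, whose observed statistic ties every null
value, is not responsive. Estimating the 97.5th percentile from a finite
sample of 1000 shifts makes the realised two-sided level about 5.2% rather
than exactly 5% (the exceedance probability of the 975th order statistic
of 1000 exchangeable draws is $\approx 26/1001$ per side); the calibration
suite measures the realised level on 2000 simulated null neurons and
checks it against the 4–6% band. No multiple-testing correction is applied
across neurons at this step, mirroring the original analysis. Neurons
responsive in at least one of the three sessions enter downstream analyses
(`session_union_filter()`); note that this union necessarily passes
$1 - 0.95^3 \approx 14\%$ of truly null neurons, so recovery specificity
is a property of the per-session test, not of the union.

Whether the raw fluorescence or the ΔF/F0-level activity should be rotated
is not fixed by the method's description; the default rotates the
fluorescence jointly with its slow baseline (exact and fast), and
`rotate = "raw"` recomputes $f_0$ on every rotation (two orders of
magnitude slower, supported for comparison).

## Ensemble discovery

Trial-mean responses from 1 s before to 2 s after onset are binned at
0.1 s, and the three sessions are concatenated, giving a 90-dimensional
feature vector per neuron. Features are column-centred but *not* variance
scaled before PCA — the clusters differ precisely in amplitude and sign,
which z-scoring would distort. Neurons are projected on the first four
principal components (a warning is raised if those explain less than 60%
of variance) and clustered by Euclidean k-means with 50 seeded restarts;
the number of clusters is selected by maximum mean silhouette width over
k = 2…6, with ties broken toward the smallest k. For k = 2 the cluster
whose session-1 post-minus-pre contrast is larger is labelled the
stimulus-activated ensemble; exact ties break deterministically with a
warning. With the default population mix (which includes a nonresponsive
fraction) bootstrap false positives enter the included set as a third,
flat cluster and the silhouette may legitimately select k = 3; the
two-ensemble recovery checks therefore plant a pure
activated/inactivated mixture (62%/38%).

## The imaging forward model

`simulate_session_set()` generates per-ROI fluorescence as
$f = F(1 + c(t)) + d(t) + \varepsilon(t)$: a tonic calcium level (0.3
ΔF/F0 units), Poisson background spiking (0.2 Hz) convolved with a
double-exponential indicator kernel (rise 0.2 s, decay 1.6 s, GCaMP6s-like
— chosen to produce second-scale transients), a deterministic evoked
transient per stimulus, sinusoidal drift (period 200 s) and white noise
(SD 0.05 in fluorescence units against a baseline of 1). Planted activated
neurons receive a positive transient of peak amplitude 0.5 ΔF/F0 (±10%
per-neuron heterogeneity); inactivated neurons a negative transient capped
at 80% of the tonic level plus suppression of background spiking during
the stimulus; session 2 scales evoked responses by the optogenetic gain
(default 1.5). A neuron whose planted amplitude is zero is ground-truth
nonresponsive, so `evoked_amplitude = 0` yields an exact null population.
The background-overlap trace is an offset plus shared low-pass noise, so
the $f_0$ definition (ROI + background) is exercised nontrivially.
Stimulus schedules draw inter-stimulus intervals uniformly within
configured bounds, rescaled into the session's free time so a drawn
schedule is never infeasible; sessions are freely shrinkable because every
analysis window is specified in seconds. Withdrawal flags threshold the
noisy summed activated-population response. What the simulator does *not*
emulate: pixel-level movies, motion artifacts, CNMF source-extraction
errors, or cross-session ROI mismatches — passing recovery tests therefore
validates the analysis chain, not the upstream segmentation.

Default test problem sizes — 2000 neurons × 300-s sessions for
calibration, 200 neurons for recovery — were chosen as the smallest sizes
at which the binomial error of the measured rates is well inside the
asserted bands.

## Intrinsic electrophysiology

Features follow their operational definitions on 1-s current steps
(−50…+50 pA, 10 pA increments, 20 kHz): input resistance is the slope of
the median steady-state deflection (last 0.3 s of the step, the same
window the sag definition uses) against current over non-spiking ±30 pA
sweeps; the membrane time constant is a single-exponential least-squares
fit over the first 0.1 s of relaxation on the −50 pA sweep (initialised
log-linearly; `nls` with a scale offset so noiseless traces converge); the
sag ratio divides the median deflection over the last 0.3 s by the minimum
deflection in the first 0.3 s. Action potentials are detected where
dV/dt — central differences on a zero-phase 3-kHz Butterworth-filtered
copy, mirroring the acquisition filter — first crosses 50 V/s; the
threshold is the voltage at that crossing, the amplitude is peak minus
threshold, and the first-spike latency is measured to the *peak* of the
first AP (as operationally defined, although threshold-referenced
latencies are more common). The first-AHP latency runs from the threshold
crossing to the post-spike minimum, bounded by the next spike's threshold
or the step end, and a minimum sitting on the search boundary is flagged
as truncated. The depolarising hump has two rule variants — threshold
minus the 0.3-s potential for early-spiking cells, maximum in the first
0.3 s minus the 0.3-s potential for delayed-spiking cells — and both are
always computed.

Layer-1 interneurons are classified from (first-spike latency, first-AHP
latency). The numeric boundaries are configuration (defaults 0.1 s and
12 ms, between the two simulated archetypes); when no thresholds are
given, a two-component Gaussian mixture on the log latencies of a
recorded population is the fallback, labelling the longer-latency
component neurogliaform-like. Values exactly on a boundary tie-break
toward pNGF with a warning.

The sweep simulator produces idealised waveforms on purpose: passive
exponentials with a closed-form sag bump (Gaussian, centred 0.2 s into the
step) so the planted sag ratio is $|IR|/(|IR| + d_{sag})$ exactly, and
stereotyped spikes whose first suprathreshold sample carries exactly the
planted threshold voltage. This is what makes 2%-level recovery assertions
meaningful; it is not a biophysical neuron model.

## Feedforward IPSC isolation

Compound postsynaptic currents recorded near −50 mV contain an EPSC
followed, with some probability per trial, by a disynaptic outward IPSC;
recordings at −92 mV (the GABA-A equilibrium potential) contain the EPSC
alone. The feedforward IPSC is isolated by scaling the averaged pure EPSC
so its initial slope matches the initial slope of the averaged compound
PSC, then subtracting. Onsets are located at the first 5%-of-peak crossing
on a 3-kHz-filtered trace (searching back from the peak so late noise
cannot pre-empt the onset); because both onsets use the same fractional
criterion on kernels with matched rise times, the detection bias cancels
in the EPSC-to-IPSC latency. The initial-slope fit uses a 0.5-ms window:
a 1-ms window would overlap an IPSC of sub-millisecond latency and corrupt
the scale factor in precisely the recordings the latency exclusion rule
must catch. Exclusion rules mirror the antidromic-contamination logic:
a recording is dropped when outward IPSCs appear in 100% of −50 mV trials
(detected per trial as excursions above 3 baseline SDs within 1–20 ms
after the EPSC onset — the detection window must extend well past typical
3-ms latencies) or when the measured latency is below 1 ms. With Bernoulli
release at probability $p$, the averaged isolated IPSC has amplitude
$p \times$ the planted single-trial amplitude — an identity the tests
assert — so amplitude-recovery checks use deterministic release. Inward
charge is the trapezoidal integral of the negative-rectified,
baseline-subtracted current (pA·s = pC, reported positive), making it
additive over windows and invariant to outward components.

## Statistics

The comparisons delegate to standard implementations (`friedman.test`,
`wilcox.test`, `fisher.test`, `chisq.test`, `t.test`); the package's job
is the family bookkeeping: Bonferroni corrections use the family size of
each figure-style comparison (e.g. sessions 2 and 3 against session 1 →
family 2), and corrected p-values are clamped to [raw p, 1]. Dunn's post
hoc test after the Friedman omnibus is implemented in the package (no
installed package provides it): pairwise z statistics on mean within-block
ranks with the tie-correction factor
$C = 1 - \sum(t^3 - t)/(nk(k^2-1))$ in the standard error — the
tie-corrected variant was chosen because calcium-derived summaries
frequently tie after binning. Degenerate inputs (identical paired
samples) are flagged rather than tested. The responsive-proportion trend
runs an omnibus chi-squared over the three sessions followed by
session-1-referenced Fisher exact tests with family-2 Bonferroni.

## Interfaces and reproducibility

Traces, events and sweeps are stored as plain CSV matrices plus YAML
metadata with atomic writes and validated, lossless round-trips; configs
round-trip through YAML with unknown keys rejected. The exported
functions, `run_pipeline()` (simulate → ΔF/F0 → responsiveness → metrics →
ensembles → statistics) and this vignette are the package's interface.
Every stochastic step takes an explicit integer seed, and identical
configurations yield bit-identical outputs, which the test-suite asserts
end to end.

## Known limitations

* The simulators are validation instruments, not data emulators: real
  CNMF output has correlated noise, segmentation errors and cross-session
  drift that the recovery tests do not probe.
* The divisive $f_0$ normalisation compresses large or sustained
  transients; quantitative amplitude comparisons are only meaningful
  within a fixed windowing convention.
* The union-inclusion filter trades specificity for sensitivity by
  construction; population-level proportions of responsive neurons should
  be interpreted against its $\approx 14\%$ null inclusion rate.
* Classification boundaries for interneuron types are configuration;
  transferring them across preparations requires re-estimation.
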