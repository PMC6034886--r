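---
title: "Methods and numerical choices in striavis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical choices in striavis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striavis)
```

striavis implements an analysis pipeline for extracellular recordings from
the rodent dorsomedial striatum under two visual-stimulation regimes: a
passive protocol (drifting gratings and full-screen luminance blinks shown to
a stationary animal) and an active protocol (a linear maze whose projected
wall pattern switches between uniform gray and a stationary grating, so that
visual motion is generated by the animal's own running). Every analysis has a
matching synthetic-data generator with exact ground truth, so each estimator
can be validated end to end. This vignette documents the models, the
parameter defaults, and the numerical decisions that are not obvious from the
function reference.

## Synthetic units and classification

`gen_unit()` draws interspike intervals as a fixed refractory/suppression
dead time followed by a mixture of a truncated exponential (intervals below
2 s) and, with the archetype's `isi2s_fraction`, a shifted exponential beyond
2 s. The short-interval rate is solved numerically so the overall mean rate
matches the archetype exactly; this is the simplest renewal process that
realizes all the features the classifier consumes (rate, fraction of
intervals above 2 s, post-spike suppression). Classification
(`classify_unit()`) applies the rules in a fixed order: the 2% ISI2s cut
first (phasically firing), then narrow/fast/short-suppression (fast-firing),
then slow/long-suppression (tonically firing); only the 2% cut is a published
convention, the remaining thresholds are package defaults exposed through
`class_thresholds()`.

Spike width is measured on the linearly detrended mean waveform as the full
width of the trough at half amplitude, with the baseline taken from the
waveform edges; the edge baseline matters because a symmetric measurement
against the global mean biases the width of asymmetric spikes.

## Passive visual responses

`pvis_responsivity()` compares, per grating condition, the trial-wise firing
rates of the stationary and the moving epoch against the preceding
uniform-gray epoch with paired tests at per-test alpha = 0.05, and flags a
unit responsive when at least two conditions are significant in either
comparison. Note the arithmetic of that rule: under the null each condition
is flagged with probability of roughly `1 - 0.95^2` (two correlated
level-0.05 tests), so about 2.3 of 24 conditions are expected significant by
chance and the responsive flag itself is deliberately liberal on null units.
The per-test p-values are calibrated (the test suite checks this); users who
need a conservative screen should raise `min_significant` or lower `alpha`.

## Linear-maze analyses

Trajectories are linearized by orthogonal projection on the track axis,
smoothed with a 10-frame Gaussian and rounded to 1% of track
(`linearize_positions()`). `extract_trials()` finds midtrack crossings and
extends them in both directions until running speed falls below 5 cm/s,
discarding runs that stall inside the central 10-90% span. Rate maps
(`occupancy_rate_map()`) use 20 equal bins over that span.

The label-shuffle test (`shuffle_significance()`) builds, per trial, an
occupancy-normalized rate vector, smooths the striped-minus-uniform
difference curve with a 5-bin moving average (shrinking at the edges), and
compares it against 1,000 surrogates obtained by shuffling the condition
labels. Local boundaries sit at the 2.5% tails of the per-bin surrogate
distributions, placed halfway between the bracketing order statistics. The
global (family-wise) boundary then scales the local boundaries continuously
outward from the per-bin surrogate median until exactly 5% of the surrogates
cross anywhere; the continuous scaling lets surrogates drop out one at a
time, so the achieved breaking fraction equals the target up to the
1/1,000 granularity, and the family-wise false-positive rate across
independent null sessions calibrates at 5%.

The maze generator (`gen_maze_session()`) uses constant-speed runs
(85 cm/s default) separated by Gaussian reward-zone dwells (25 ± 5 s), with
spikes from an inhomogeneous Poisson process: a Gaussian place field,
a multiplicative condition factor `g = (1 + MI)/(1 - MI)` applied on striped
trials so the ground-truth modulation index is exact in expectation, an
optional linear speed gain, and an optional sinusoidal stripe-phase
modulation whose depth equals the circular modulation index of the phase
tuning in expectation.

## LFP analyses

Band-pass filtering defaults to applying the squared magnitude response of
the 8-pole Butterworth band-pass in the frequency domain (`bandpass(method =
"fft")`). This is the exact steady-state equivalent of zero-phase
forward-backward filtering, and it is used as the default because the
recursive implementation (`signal::filtfilt`) diverges to NaN for very
narrow, very low passbands relative to the sample rate — the delta band
(1-4 Hz) at 1,250 samples/s being the practical case. Where both are stable
the two methods agree to r > 0.999.

Spike-LFP coupling (`spike_phase_coupling()`) bins spike phases at 18
degrees, smooths with a 5-bin circular moving average, and reports the
modulation index `(max - min)/(max + min)` of the smoothed histogram plus a
Rayleigh test. The phase-locking generator inverts exactly this pipeline: a
requested locking strength is converted to a von Mises concentration by
deterministic numerical integration of the von Mises density through the
same binning and smoothing, and spikes are kept by von-Mises-weighted
thinning (`phase_locking_kappa()`, `gen_lfp()`).

`granger_pair()` fits restricted and full autoregressions by least squares
for every whole-sample lag between 2 and 40 ms and reports the F statistic
of the restriction per order, displaying the order with the largest F. At a
fixed order the statistic is identical to the standard two-model Wald F (the
test suite verifies exact agreement with an independent implementation), and
the null false-positive rate at a fixed order matches alpha.

## The lag-by-frequency cross-correlation map

`tf_lagged_xcorr()` filters both channels at every integer frequency from 1
to 100 Hz with 2 Hz-wide zero-phase passbands, cross-correlates each pair of
band signals over ±100 ms in 2 ms steps, normalizes per band to correlation
units, and converts each correlogram to a magnitude via its analytic-signal
envelope. Two numerical decisions matter here:

* **Envelope identity.** The analytic signal of a cross-correlogram equals
  half the cross-correlation of the two analytic band signals. The package
  computes the envelope through that identity on the full-length records
  instead of taking a Hilbert transform of the ±100 ms correlogram itself; a
  transform of such a short segment wraps spectral energy around its ends
  and tilts the envelope deterministically. The raw signed correlograms are
  retained in the result (`$correlogram`), and the test suite checks them
  against brute-force time-domain lagged correlation.
* **Zero-lag suppression.** Synchronous, zero-lag-symmetric components
  (e.g. shared recording artifacts) are removed by subtracting from each
  lag the minimum of the symmetric ±lag pair. This cancels any exactly
  lag-symmetric component and zeroes lag 0. The suppression acts on
  magnitudes, which are a nonlinear function of the band signals: a
  synchronous tone that shares a band with leaked delayed content leaves an
  interference residue of the size of the leakage, so shared artifacts are
  only cleanly removed when they are spectrally separated from the delayed
  components of interest.

One structural limitation follows from the pinned 2 Hz bandwidth: a 2 Hz-wide
band signal decorrelates over roughly a second, so every correlogram envelope
is far broader than the ±100 ms window. After suppression the map rises
monotonically away from zero lag toward the true delay, which biases the
*position* of the suppressed maximum outward within the window. Domain
counts, their frequencies, and the sign of their lags are reliable; the
precise lag of a domain peak is not, and should be read from the signed
correlograms or a wider analysis window when it matters.

`count_xcorr_domains()` thresholds the suppressed map at mean + 3 SD and
counts 8-connected components, ignoring components smaller than 10 cells:
the iterative filters smear any genuine band-limited lagged interaction over
many frequency rows and lag columns (tens to hundreds of cells), so
near-threshold single-cell specks are noise by construction.

The demonstration generator `gen_lfp_pair_s8()` builds a pair containing a
phase-delayed theta oscillation, two time-delayed gamma burst trains, and a
coincident square wave: the suppressed map shows one domain per delayed
component and no trace of the synchronous artifact. Its construction encodes
the constraints above — the theta component is narrowband *noise* (a
constant-amplitude tone has a flat correlogram envelope that the suppression
cancels identically), the square wave is generated with integer half-period
arithmetic (floating-point zero-crossing tests inject pseudo-random
broadband flips), and the artifact frequency (50 Hz, mains-like) is kept
away from the delayed components' bands.

## Histology density quantification

`detect_somata()` performs scale-normalized Laplacian-of-Gaussian matched
filtering at the expected soma width (14 px default), keeps local maxima
with a minimum separation (7 px default) above a response threshold of 1 SD,
and enforces the separation with greedy non-maximum suppression — plateau
ties from equal blobs would otherwise survive the local-maximum test.
`threshold_axons()` flags pixels above mean + 4 SD of the nonmasked
luminosity. `binned_density()` normalizes per 10 × 10 grid cell by the
nonmasked area, invalidating cells with fewer than 2,600 valid pixels, and
`density_correlation()`/`quartile_analysis()` compare two density grids over
jointly valid cells.

## A short worked example

```{r example, eval = FALSE}
cfg <- session_config(n_trials = 40)
ses <- gen_maze_session(cfg, list(
  maze_unit_spec(base_rate_hz = 5, visual_mi = 0.3)))
pos <- linearize_positions(ses$positions[, c("x_cm", "y_cm")])
res <- shuffle_significance(ses$spikes[[1]], pos, ses$positions$t,
                            ses$trials)
print(res)
```
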