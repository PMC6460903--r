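---
title: "hfokit: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hfokit: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the methods it
implements: the signal models and statistics, the tunable parameters
with their defaults and provenance, what the synthetic-data generator
does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem

High-frequency oscillations (HFOs) are brief (tens of milliseconds)
oscillatory EEG events above 80 Hz: *ripples* in 80–250 Hz and *fast
ripples* in 250–500 Hz. Their rate and localization carry clinical
information about the seizure onset zone. Automated analysis is a
three-stage chain: band-limiting preprocessing, detection of candidate
events of interest (EOIs) on the band-limited trace, and
classification of each EOI into ripple / fast ripple / artifact. The
notorious artifact class is the *false ripple*: band-pass filtering a
sharp broadband transient (an epileptic spike) yields the filter's own
oscillatory impulse response, which an energy detector cannot
distinguish from a genuine HFO. Classification therefore has to look
at the event's spectral structure in the *unfiltered* signal.

## 2. Data model and coordinates

A `Recording` is an ordered list of epochs; an epoch is a set of named
channels that span the same duration (per-channel sampling rates may
differ; cross-channel operations require equal rates and fail
otherwise). Event markers are rows of a sorted data frame
(epoch, channel, onset, duration, label, optional properties).

All internal times are seconds; sample indices are 0-based; intervals
are half-open `[start, end)`; seconds-to-samples conversion floors at
both interval ends. These conventions make segmentation conserving: a
partition of `[0, T)` into windows yields epochs whose sample counts
sum exactly to the original count.

EDF/EDF+C is the interchange format (16-bit integers; the default
physical range ±3276.8 µV gives a 0.1 µV quantization step, and the
round-trip error bound `range/65536` is asserted in the tests).
Multi-epoch recordings are serialized one file per epoch — the
external format has no standard multi-epoch container — and only the
continuous dialect is supported; EDF+D is rejected. Because EDF+ TAL
annotations carry no channel field, the writer encodes markers as
`label@@channel` in the annotation text and the reader splits them;
foreign files without the suffix get an empty channel. Instantaneous
annotations (no duration field) are given a 1 ms token duration so the
positive-duration invariant holds.

## 3. Synthetic EEG: the stated world

The generator exists so that every downstream stage can be tested
against exact ground truth. Per channel it produces:

* **Background**: Gaussian noise spectrally shaped to power ∝ 1/f
  (exponent 1, the classic EEG broadband slope), rescaled to a target
  SD (default 25 µV). The log–log periodogram slope is checked to be
  −1 ± 0.2 averaged over 20 seeds. R's default Mersenne-Twister
  generator is seeded explicitly; every output is a pure function of
  (config, seed).
* **HFO bursts**: `amplitude · sin(2π f₀ t)` over `n_cycles / f₀`
  seconds with Hann on/off ramps over a `taper` fraction (default
  0.25) of the burst at each end; the taper avoids spectral splatter
  that would confound the classifier tests. Ground-truth label: `R`
  below 250 Hz, `F` at or above. Amplitudes are specified in units of
  the background's *in-band* SD (the SD of the ideally band-limited
  background component, computed spectrally by `band_sd()`), so that
  "5× SNR" means the same thing at 120 Hz and at 400 Hz.
* **Spikes**: a difference of two Gaussians — a sharp positive lobe of
  ~5 ms base width minus a shallow (0.05 weight), three-times-wider,
  delayed undershoot. The weights matter: the net low-frequency
  content stays positive and the magnitude spectrum decays
  monotonically from low frequencies, as for a real sharp transient.
  (An earlier, nearly zero-mean variant turned out to be a band-limited
  wavelet with a spectral peak near 180 Hz — i.e., itself an
  oscillation — which would defeat the purpose of the artifact class.)
  Ground-truth label: `A`.

Stochastic datasets place a configured number of events per class with
a minimum onset-to-onset gap by rejection sampling; infeasible
densities are an error.

What the generator does **not** emulate: sleep architecture, eye and
muscle artifacts, electrode drift, line noise, spatial correlation
across channels, and the heavy-tailed amplitude distributions of real
interictal activity. A green test on this world establishes that the
algorithms implement their definitions and recover a known signal at a
stated SNR — not clinical performance.

**Event density.** The acceptance calibration scenario fixes amplitude
(5× in-band SD) and event count (20) but not duration. It is set to
120 s (10 events/min, ~1% duty cycle) because the detectors' whole-epoch
`mean + n·SD` threshold convention presumes the sparse-event regime it
has clinically; at several events per second the events themselves
inflate the threshold statistics and the convention breaks down by
construction.

## 4. Preprocessing

**Windowed-sinc FIR.** Kernels are Blackman-windowed sincs: low-pass
normalized to unit DC gain; high-pass by spectral inversion; band-pass
as the convolution of the high-pass at the lower edge with the
low-pass at the upper edge; optional self-convolution squares the
frequency response. Default length 513 taps (~256 ms at 2 kHz) —
chosen because it reaches the quoted stop-band floor with a practical
transition width; the Blackman window's single-pass floor is ≈ −74 dB
and the self-convolved band-pass measures ≈ −150 dB (asserted ≤ −145).
The stop band is measured outside the pass band widened by the
standard windowed-sinc transition estimate `tw = 4·rate/taps`.
Application is linear convolution via FFT with the group delay
`(L−1)/2` compensated, so output is time-aligned with input (one-pass
delay compensation was chosen over forward–backward filtering; with a
symmetric kernel the compensated response is already zero-phase, which
the cross-correlation test verifies). Edges are zero-padded.

**EMD.** Sifting subtracts the mean of the cubic-spline envelopes
through local maxima and minima; one IMF's sifting stops when
`sum((s−d)²/s²) ≤ ε` (default ε = 0.2, the customary threshold from
the EMD literature), with a machine-epsilon-scaled floor guarding
zeros of `s` and a hard cap of 200 inner iterations. Envelope
endpoints mirror the two nearest extrema beyond each signal end (the
common anti-drift boundary rule). The outer loop stops at the
requested IMF count or when the remainder has fewer than two extrema
of either kind or is numerically linear. Completeness (IMFs + residual
reconstruct the input to 1e−8 relative) holds by construction and is
asserted. `emd_highpass()` recomposes a contiguous leading subset of
IMFs, which acts as an adaptive high-pass.

## 5. Detection

Both detectors share one run pipeline on a band-limited channel:
energy trace → threshold at `mean + n·SD` over the whole epoch → merge
supra-threshold runs closer than `merge_gap_s` → drop runs shorter
than `min_duration_s` → require at least `min_peaks` strict local
maxima of the rectified signal above its own `mean + 3·SD`. Merging
precedes the duration test (the order is not fixed in the source
literature; merge-then-test is the more permissive reading and is
documented here as the implemented one). Defaults come from the cited
detector literature: RMS — 3 ms window, 5 SD, 6 ms, 6 peaks, 10 ms
gap; Hilbert envelope — 3 SD, 10 ms, 6 peaks, 10 ms gap. Threshold
statistics over the full epoch (not a sliding baseline) match the
published rules; a sliding baseline is a documented extension point.

## 6. Stockwell-transform classification

The S-transform is computed in its FFT formulation (row `n` is the
inverse FFT of the spectrum shifted by `n` and windowed by
`exp(−2π²m²/n²)`); the test suite checks it to 1e−8 against a direct
O(N²) evaluation of the definition with the time-domain Gaussian
window `f/√(2π)·exp(−t²f²/2)`.

For one EOI: take the event ± `context_s` (default 100 ms), zero-pad
to ≥ 1 s effective length so rows sit on a ≤ 1 Hz lattice, transform,
and average the magnitude columns over `avg_window_s` (default 10 ms)
around the time of the maximum absolute amplitude inside the EOI. In
this profile, the high-frequency peak is the largest local maximum in
[60, 500] Hz; scanning downward from it, the first local minimum is
the trough and the first local maximum below the trough is the
low-frequency peak. HFO ⟺ both exist and `profile[HF]/profile[trough]
≥ θ` (default θ = 2; the source rule prints no threshold, so it is a
parameter); ripple vs fast ripple splits at 250 Hz; anything else is
`A` with a reason code. The label is invariant to amplitude scaling,
and a frequency sweep across 250 Hz flips R→F at the boundary (both
property-tested).

Two numerical guards make the geometry well-defined on a 1 Hz
lattice: the profile is boxcar-smoothed over ±3 Hz before the extrema
scan (otherwise lattice-scale noise wiggles manufacture spurious
troughs), and a "low-frequency peak" must exceed `1e−3` of the HF
peak to count as structure (otherwise the numerical floor below a
band-pass filter's stop band — at −70 dB or less — provides a fake LF
peak and every filtered transient would pass the isolation test).
Both are exposed parameters.

**Known limitation.** On noisy backgrounds a large sharp transient
genuinely resembles an HFO in the instantaneous S-spectrum: the
transform's frequency-proportional time resolution turns an impulse
into a stripe whose magnitude *grows* with frequency until the spike's
own spectral roll-off, so the profile can show an apparently isolated
high-frequency maximum. At θ = 2 the rule rejects only roughly half of
5–8× SD spikes riding on 1/f background (measured across seeds during
development). The clean filtered-spike fixture in the acceptance tests
is rejected deterministically (no low-frequency structure exists at
all); users should treat θ as the sensitivity/specificity dial it is.

## 7. SVM stage

Scaling is the linear map `x' = m + (x − x_min)(M − m)/(x_max −
x_min)` per feature (defaults m = 0, M = 1); out-of-range values at
application time extrapolate (no clipping); constant features map to
`m`.

Feature-subset selection runs `n = ⌊1/r⌋` outer iterations (r =
validation ratio): shuffle, hold out `⌊rows·r⌋` samples, fit the
scaler on the training subset only, rank features by one-way ANOVA F
(constant features get F = 0 and sort last, stable), then greedy
forward selection: starting from the empty set with the
majority-class accuracy as baseline, each round trains one SVM per
remaining candidate and keeps the best strictly-improving feature;
candidates whose trial accuracy fell below `mean − sd` of the round's
accuracies are dropped from further consideration; the loop stops when
no candidate improves. Subsets are aggregated into an occurrence
histogram and features appearing at least twice (configurable) form
the final subset. Accuracy is the plain fraction correct on the
validation subset. One seeded generator drives the whole procedure
with per-iteration derived streams, so results are exactly
reproducible.

The final model refits the scaler on the entire training set, tunes
(C, γ) by exhaustive grid search with stratified 3-fold
cross-validation (default grids C ∈ 2^{−5,−3,…,15}, γ ∈
2^{−15,−13,…,3}, from the practical guide this grid convention comes
from; ties break to the smallest C, then the smallest γ), and fits an
RBF-kernel C-SVC. Multi-class is one-vs-one with majority voting,
ties to the earliest class in sorted order. The quadratic program is
solved by a compact SMO implementation (maximal-violating-pair
working-set selection) compiled from `src/` — the deployment
environment provides no SVM library, so the solver is internal; its
solutions are verified against the KKT optimality conditions in the
test suite, which is solver-independent. Models serialize to a
versioned JSON container (scaler, subset, C/γ, support data) and
round-trip with bit-identical predictions.

Design notes where the design was genuinely open:

* The final (C, γ) search is an independent grid on the full training
  set; it does not reuse the selection-phase folds.
* Unmatched detections fold into a generic `EOI` class when reference
  markers carry no explicit artifact label (`relabel_by_reference()`);
  matched events take the reference label (overlap of the shorter
  event ≥ threshold, same channel and epoch).
* The accuracy experiment for the acceptance suite uses a 4-SD
  class-mean separation: the 3-SD layout used for the
  selection-recovery experiment has a Bayes accuracy of ≈ 0.90
  (verified with a nearest-class-mean oracle), so a ≥ 0.9 bar is only
  attainable in a world with more separation. The selection experiment
  keeps the 3-SD world.

## 8. Evaluation and reports

Matching normalizes temporal overlap by the *shorter* event
(containment counts as full overlap, matching visual-marking
practice), requires identical channel and epoch, and pairs greedily in
descending overlap order with ties to the earlier onset — one-to-one,
deterministic. Per-class counters follow the standard bookkeeping
(correct → P_T of the class; wrong → N_F of the true class and P_F of
the predicted class), and the derived statistics are sensitivity
P_T/(P_T+N_F), precision P_T/(P_T+P_F), FDR P_F/(P_T+P_F), F1, and a
false negative rate reported as 1 − sensitivity (no independent
formula exists for it in the source material). Undefined 0/0 ratios
are reported as missing, never as 0. The HFO report gives per
channel × label counts, percentages, mean duration, mean inter-event
interval (previous offset to next onset — gap-based IEI is robust to
duration differences), and a channel × time occurrence matrix; the
correlation report splits one event list into reference and test
label sets and scores them with the same matcher.

## 9. Process pipeline

Activity modules live in a registry (`register_activity()`): FIR and
EMD filters, both detectors, the Stockwell and SVM classifiers, and
the two feature extractors; `bump_modeling` is a reserved slot whose
execution fails with a clear message (the published description of
that classifier is one line and not implementable faithfully).
Process definitions are XML (`processList/process/moduleList/activity`
with `inputList` and `outputList`); input references must resolve to
the primary input or an earlier activity, checked at parse time.
Execution is strictly sequential and fail-fast: the first failing
activity yields an error vector (activity, stage, message) and no
outputs are registered; activities never mutate their inputs; a
monitor callback reports start/done per activity. Parameter sets
persist in a JSON store keyed by (process name, set identifier). Six
preset definitions ship under `inst/processes/`.

## 10. Numerical choices, in one place

* Seconds→samples: floor at both ends of half-open intervals.
* Population (divide-by-n) standard deviations in the feature
  formulas; fixed for determinism.
* Local extremum = strictly greater/smaller than both neighbors;
  plateaus contribute their first sample.
* Spectral bins are half-open `[f, f + bin_hz)`; `⌈(f_hi−f_lo)/bin_hz⌉`
  bins; a partial last bin is kept.
* EMD stop-criterion denominator floored at machine-epsilon × signal
  scale; 200-iteration sifting cap; envelope mirroring at ends.
* Stockwell profile: ±3 Hz boxcar smoothing; LF-structure floor 1e−3
  of the HF peak; 1 Hz rows via zero-padding to ≥ 1 s.
* Matching overlap clamped to [0, 1] against floating-point spill.
* Grid-search ties → smallest C, then smallest γ; voting ties →
  earliest class in sorted (byte order) class list.

## 11. Honest red: the RMS sensitivity bar

The acceptance suite asserts sensitivity ≥ 0.9 for *both* detectors on
the calibrated world (5× in-band SD, 20 events). The Hilbert detector
meets it (sensitivity 1.0, precision ≥ 0.94 on the fixed seed). The
RMS detector at its literature defaults measures ≈ 0.85: at a 5× SNR
the threshold margin is only ~1.2×, supra-threshold spans are 10–15 ms,
and a 10–15 ms span physically cannot contain six rectified peaks below
~190 Hz — the published validation of the same rule reports ~84%
sensitivity, so the 0.9 bar is optimistic for this detector. The
assertion is kept (and fails) rather than weakening the bar or tuning
the stated world; see the decisions ledger accompanying the
repository.
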