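---
title: "Detecting NREM oscillations and quantifying their hemispheric laterality"
author: "sleeposc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting NREM oscillations and quantifying their hemispheric laterality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeposc)
```

## The problem

After a hemispheric stroke, the microarchitecture of non-rapid eye movement
(NREM) sleep changes over the lesioned cortex: slow oscillations (SOs,
0.1–1 Hz waves with a prominent positive "UP state" peak before a deep
trough), delta waves (1–4 Hz waves with a deep trough but only a small
positive peak), sleep spindles (10–16 Hz bursts of at least half a second),
and the temporal nesting of spindles to slow events all shift in density.
SO-nested spindles are associated with consolidation and recovery, while
delta-nested spindles are considered pathological; the balance between the
two, compared across hemispheres, is therefore a candidate bedside marker of
post-stroke sleep physiology.

`sleeposc` implements the full analysis chain for this question: rule-based
event detection on referential scalp EEG restricted to NREM epochs,
SO/delta-nested spindle identification, per-channel densities (events per
retained NREM minute), hemispheric laterality indices (LI), the
SO-nested/delta-nested LI ratio, topographic maps, and cohort statistics
(paired t-tests, one-way ANOVA across medication groups, and linear
mixed-effects models with Cohen's *d* effect sizes). Because clinical EEG of
this kind is rarely shareable, the package also contains a seeded
synthetic-EEG generator with ground-truth annotations so that every stage is
testable end to end.

## Detection rules

All thresholds are derived from the data of the channel being analysed, so
detection is invariant to per-channel gain.

**Slow waves.** The signal is band-limited to 0.1–4 Hz: a 0.1 Hz high-pass
followed by a 4 Hz low-pass, each a 4th-order Butterworth applied
forward–backward (zero phase), because event *timing* anchors the nesting
window and must not be skewed by filter delay. Every positive-to-negative
zero crossing defines a candidate wave: its peak is the maximum since the
previous negative-to-positive crossing, its trough the minimum until the
next one. Two percentile thresholds are computed per channel — the 40th
percentile of trough amplitudes (so troughs below it are the deepest 40%)
and the 85th percentile of peak amplitudes (peaks above it are the top 15%).
A candidate with a deep trough and a high peak whose peak-to-trough lag is
150–500 ms is an SO; a deep trough with a *sub-threshold* peak within 500 ms
is a delta wave. The 150 ms lower bound is not applied to delta waves (the
rule that defines them says only "within 500 ms"); a flag restores it.
Percentiles use linear interpolation between order statistics
(h = (n−1)p + 1), chosen as the most common convention and documented so
results are bit-stable.

**Spindles.** The signal is band-limited to 10–16 Hz and the magnitude of
its analytic signal (Hilbert transform, computed by the standard FFT
construction) is smoothed with a unit-area Gaussian window of 200 ms support
(sd = support/6, truncated and renormalized). With μ and σ the mean and
sample (n−1) standard deviation of that envelope over the channel's retained
NREM samples, a spindle is a maximal run above μ + 1.5σ lasting at least
500 ms and containing at least one sample above μ + 2.5σ. Runs are never
merged, have no maximum duration, and are discarded whole if they touch a
masked-out sample. μ and σ are computed once per channel over all retained
NREM data — not per epoch — since the rules define them on "the signal"
without finer granularity.

One realization detail: the spindle band uses a single 4th-order Butterworth
*band-pass* rather than cascaded high/low-pass sections. Forward–backward
filtering squares each section's response, and for a band this narrow a
squared cascade sags to a gain of ~0.74 at 12 Hz, which would bias every
envelope amplitude; the single band-pass keeps mid-band gain at 0.998. The
slow band keeps the literal high-pass + low-pass cascade (its passband gain
at 0.8 Hz is 0.99998).

**Masking.** A 30-s-epoch hypnogram (N1/N2/N3 collapse to NREM by default)
selects the NREM samples; any sample whose absolute amplitude exceeds
500 µV (configurable) is treated as artifact and removed together with 1 s
on each side, per channel. Masked samples are excluded from event search
*and* from the density denominator, so densities remain counts per retained
NREM minute. Events whose defining samples touch masked regions are dropped
whole rather than truncated.

## Nesting

A spindle nests to a slow event when its envelope peak falls within −0.5 to
+1.0 s of the slow event's UP-state (positive) peak. The 1.5 s total span is
anchored asymmetrically around the UP state; SO nesting and delta nesting
are evaluated independently with the same window, so one spindle can count
once in each tally. Within a kind the pairing is one-to-one: candidate pairs
are accepted greedily by increasing |lag|, ties toward the earlier slow
event, and neither member is reused. One-to-one matching is the only rule
under which nested counts are bounded by *both* parent counts — a property
the rest of the pipeline (densities, LIs) relies on.

## Densities, laterality and statistics

Densities are counts per retained NREM minute, per channel, for five event
types: SO, delta, spindle, SO-nested spindle, delta-nested spindle. For
stroke subjects the laterality index of a type is the mean density over the
perilesional (stroke) electrodes divided by the mean over all contralateral
electrodes (CM ∪ CNM; a flag restricts the denominator to the mirrored CM
set, which some electrode-wise comparisons use). For healthy subjects it is
left over right, inferred from 10–20 label parity unless configured. LI = 1
means symmetry; the LI *ratio* divides the SO-nested-spindle LI by the
delta-nested-spindle LI, so values below 1 indicate relatively stronger
lateralization of the pathological nesting.

The cohort model is a linear mixed-effects fit by maximum likelihood,

    density ~ electrode_class + (1 + electrode_class + medication_group | patient)

with electrode class coded 0 = contralateral, 1 = stroke. The fit is
delegated to `lme4`; the p-value of the fixed electrode effect uses the
Satterthwaite approximation (`lmerTest`), which keeps the test close to
nominal size at realistic cohort sizes (five patients). When the full random
structure is singular or fails to converge — common with so few patients —
the model falls back, with a warning, to a random intercept + electrode
slope, then to an intercept only. R² is the squared correlation between
fitted and observed densities (an overall-model convention). Cohen's *d*
standardizes the fixed electrode effect by the square root of the summed
random-effect variances plus the residual variance; a residual-only
standardizer is available by flag. |d| of 0.20/0.50/0.80 reads as
small/medium/large. Zero-variance degeneracies in the t-test and ANOVA are
flagged (t = 0, p = 1 only when all differences are exactly zero; F = NaN
with a warning), never reported as silent numbers.

Topographic maps interpolate per-channel densities over the unit disc with a
thin-plate spline (r² log r basis plus an affine term), which reproduces the
channel values exactly at the electrodes.

## The synthetic generator: what it emulates, and what it does not

The generator builds multichannel "NREM-like" EEG: 1/f^α background noise
(spectral shaping of white noise, exact target RMS), biphasic slow-wave
templates (a positive half-sine followed by a negative half-sine,
peak-to-trough lag drawn in 150–400 ms) so injected amplitudes and timings
are exactly known, and Hann-windowed 12 Hz tones as spindles. A slow event
hosts a spindle with probability 0.3, its envelope peak at a uniform lag in
the coupling window; isolated spindles are placed clear of every coupling
window so the realized nesting fraction tracks the configured probability.
A hemispheric asymmetry factor multiplies all event rates on one side;
nesting probabilities can additionally be scaled per kind on that side. One
integer seed controls everything.

The defaults are the package's study conditions and were set once, from the
reported ranges of NREM densities and standard deep-sleep amplitudes, in the
regime the percentile rules presume (genuine waves dominating the slow
band): 200 Hz, 19-channel 10–20 montage, α = 2.5 at 6 µV RMS, SO 2.8/min
(peaks 45–70 µV, troughs −100..−70 µV), delta 4.8/min (peaks 8–14 µV, same
troughs), isolated spindles 4/min at 20 µV and 0.8–1.2 s (so the *total*
spindle rate, isolated plus nested, is ≈6.3/min). Three of those choices
deserve explanation:

* **Quasi-rhythmic slow-event times.** Slow events are placed with
  rate-exact counts on a jittered grid with ≥2 s peak spacing rather than as
  a thinned Poisson process. Thinning removes proportionally more events at
  higher rates, which biases any left/right rate ratio toward 1 and would
  corrupt asymmetry recovery; and Poisson count fluctuations at 10-minute
  recordings (~30 SOs per channel) destabilize the percentile thresholds,
  whose quotas are fractions of the candidate count. Slow-wave trains in
  deep NREM are in fact more regular than Poisson, so the choice is also the
  more physiological one.

* **Spindle duration 0.8–1.2 s.** The lower threshold is self-referential
  (μ + 1.5σ of an envelope that contains the spindles themselves), and a
  Hann burst exceeds any such threshold for only ~65–80% of its nominal
  duration. Under the 500 ms duration rule, bursts shorter than ≈0.8 s are
  undetectable *by construction*; the generator emulates detectable
  spindles.

* **Amplitude gaps.** Detection quality is governed by where the 40th/85th
  percentile thresholds land. The defaults keep the SO fraction of
  candidates just below 15% and the slow-event fraction just below 40%, with
  clean amplitude gaps between background excursions, delta peaks and SO
  peaks, so both thresholds fall into gaps rather than into an event
  distribution.

What the generator does **not** emulate: non-stationary sleep depth, real
artifact morphology (only optional high-amplitude spikes), topographic
correlation between channels (channels are independent), spindle frequency
gradients, or amplitude-based (rather than rate-based) hemispheric
asymmetry. Passing recovery tests therefore show that the *rules are
implemented correctly and recover known events in their intended regime* —
not that the method is robust on arbitrary clinical data.

One property of the detector is worth stating explicitly because the tests
are designed around it: because the thresholds are percentile quotas
computed per channel, a channel whose true event *rate* is scaled up
renormalizes its own thresholds, and detected counts partially track the
quota rather than the rate. Detection-based LI therefore compresses pure
rate asymmetries toward 1 (most strongly for SOs, whose quota is 15%).
Asymmetry-recovery checks consequently measure LI on the generator's
ground-truth densities, which is what "the LI machinery recovers the
simulated asymmetry" means; the symmetric-subject check, where both
hemispheres operate at the same point, exercises the full detection path.

## Numerical choices and degenerate inputs

* Percentile convention: `quantile(type = 7)` (h = (n−1)p + 1); σ uses the
  sample (n−1) standard deviation. Both are stated because the source rules
  name neither.
* Fewer than 5 slow-wave candidates, or an empty mask, abort detection for
  that channel with a warning rather than producing meaningless thresholds.
* Spindle onsets/offsets are reported half-open ((first supra-threshold
  sample, one past the last), so offset − onset is the run length; annotation
  files are 0-based, half-open, in milliseconds.
* Channels with zero retained NREM minutes are excluded from density tables
  with a warning; LIs with non-positive denominators are NA with a warning;
  the LI ratio propagates them.
* EDF I/O is a minimal 16-bit continuous-EDF reader/writer written with
  `readBin`/`writeBin` (no installed package provides one); mixed per-signal
  sampling rates are rejected naming the offending channels. Round trips are
  exact to one quantization step.
* Filter edge transients of the 0.1 Hz high-pass are long; the slow band
  therefore removes the mean before filtering, and tests that compare event
  sets across time shifts mask several seconds at the recording edges.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen for statistical power rather
than speed alone: detector recovery on the default 19-channel, 10-minute
subject; symmetric-subject laterality through the full pipeline at
30 minutes; asymmetry recovery from ground-truth densities over 20 seeds at
8 channels × 10 minutes; mixed-model calibration over 100 simulated null
cohorts of 5 patients × 16 electrodes. Nested-spindle events are the rarest
class (~0.84/min per channel), which is why pipeline-level ±0.1 LI
assertions cover the three primary event types; at these problem sizes the
sampling standard deviation of a nested-type LI (~0.3) exceeds that band,
and the nested types are instead validated directly on ground-truth
densities and through the nesting-fraction convergence check.

## Known limitations

* The detector inherits the percentile-quota behaviour of its rules: it
  measures *relative* prominence per channel, not absolute wave counts, so
  cross-channel density differences partially reflect candidate statistics.
* Artifact screening is a simple amplitude gate; no ICA or channel
  interpolation is attempted (out of scope by design).
* Healthy-subject LI is left/right, not re-oriented to any lesion, matching
  the definition it implements.
* The mixed model treats medication group as a random slope by patient even
  though it is a between-patient factor; with five patients the full
  structure is usually singular and the documented fallback engages. This
  mirrors the source formula rather than a statistically ideal design.
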