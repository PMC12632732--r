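---
title: "Methods: models, parameters, and design choices in mobipipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in mobipipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobipipe)
```

mobipipe analyzes dual-task mobile brain/body imaging (MoBI) sessions: a
visual Go/NoGo task performed while standing or walking, with or without
optic flow, recorded as synchronized behavioral events, heel-marker
trajectories, and multichannel EEG. This vignette documents the models the
package implements, the parameters that matter, and the choices we made
where the methodology was genuinely open.

## Behavioral scoring

Each button press is attributed to the most recent stimulus whose response
window contains it; at most one press (the first) counts per trial,
matching the definition of reaction time as *the* button press. The window
defaults to 100–1000 ms post-onset and is capped at the next stimulus
onset, so attribution windows can never overlap even though the
stimulus-onset asynchrony (400 ms stimulus + 200–400 ms ISI) is shorter
than 1000 ms. The protocol literature does not state how anticipatory or
late presses were handled; the 100 ms lower edge treats faster presses as
anticipations, and both edges are configurable.

Sensitivity is computed as `d' = z(H) − z(FA)`. Note that some reports
print the formula with the operands reversed, which would yield negative
values for above-chance performance and contradicts the positive group
means reported alongside it; we implement the standard orientation.
Because blocks can be perfect (H = 1 or FA = 0, giving infinite
quantiles), the log-linear correction — add 0.5 to each numerator count
and 1 to each denominator — is applied by default. It is continuous in the
counts and keeps every block finite; `correction = "none"` recovers raw
rates when comparing against closed-form values.

## Gait kinematics

On a treadmill, heel strike is the most anterior excursion of the heel
marker along the belt (AP) axis and heel lift the most posterior excursion
within a stride. Detection runs in three steps: candidate local maxima
(`pracma::findpeaks`, the analogue of the MATLAB routine typically used
with manual confirmation), a greedy highest-first minimum-separation
filter at 0.5 × the expected stride time, and a topographic-prominence
filter at 0.25 × the median peak-to-trough excursion of the surviving
candidate strides. Running the separation filter *before* estimating the
excursion matters numerically: with measurement noise the raw candidate
list is dominated by tiny noise bumps whose median excursion is on the
noise scale, which would make the prominence threshold vacuous. Both
thresholds replace the "visual inspection" step of manual workflows and
are exposed as arguments.

Heel lifts are the argmin of the AP coordinate strictly between
consecutive same-foot strikes, with plateau ties broken to the earliest
sample for determinism. Event times are kept at sample resolution (10 ms
at 100 Hz) with no sub-sample interpolation, matching sample-level event
definitions; stride times are therefore quantized at ±10 ms, which the
recovery tests budget for explicitly. Negative stride lengths — possible
with marker dropouts — are retained but flagged, since no published
exclusion rule exists; downstream users can drop flagged strides. Blocks
with fewer than 10 strides are summarized with a warning rather than
discarded, because partial motion data is common and the summarization
rule for such blocks is not standardized.

All metrics are invariant to AP/ML translation of the coordinate frame,
and block summaries use the sample (n−1) standard deviation in
CV% = SD/mean × 100.

## EEG preprocessing and ERP extraction

The band-pass is a Hamming-windowed linear-phase FIR kernel applied
forward and backward (`signal::filtfilt`), giving zero net phase shift.
The kernel length targets a 0.25 Hz transition band at the 0.25 Hz low
edge (≈3.3/0.25 × fs taps); since that exceeds what short recordings can
support, the order is capped at a third of the signal length with a
warning, and a signal too short even for an explicitly requested order is
an error. Average referencing subtracts the per-sample channel mean and is
idempotent.

Bad channels are *flagged* (robust z of log total power > 5, or flatline)
but never interpolated silently: the user passes a confirmed list to
`interpolate_bad_channels()`, mirroring detect-then-confirm practice.
Interpolation is a spherical spline (stiffness m = 4, Legendre series
truncated at 20 terms, ridge 1e-5) on an idealized spherical 10-10 layout
generated programmatically: midline and outer-ring anchors at 18° steps,
interior rows by spherical interpolation. ICA is deliberately out of
scope: published component-rejection criteria are rarely stated precisely
enough to reproduce, so the package neither performs nor fakes it.

Epochs span −100..800 ms around stimulus onset. At 512 Hz that window is
460.8 samples; we round each bound *inward* (ceiling/floor), giving
samples −51..409 — exactly 461 — so an epoch never exceeds the requested
window. Baseline correction subtracts the −100..0 ms mean per channel; it
is standard ERP practice though not always stated, and can be disabled.
Grand averages are formed participant-first — each participant's trials
are averaged, then participants are averaged with equal weight — so
participants with more trials do not dominate group waveforms.

Peaks are signed extrema (max for P2/P3, min for N2) within the component
window at the component electrode: P2 at FCz 200–280 ms, N2 at FCz
280–380 ms, P3 at CPz 350–500 ms. Window-edge extrema are flagged as
boundary peaks. Group-adjusted windows (e.g. a P3 window of 363–463 ms for
one group) are supported as overrides but the a-priori windows are the
default, since it is often ambiguous which set fed a published ANOVA; the
package asserts neither.

## Cluster statistics

Pointwise two-tailed t-tests run at every channel × sample on
participant-level averages: paired for Hit-vs-CR within a group, pooled-
variance independent for group comparisons of CR−Hit difference waves. A
cluster is a maximal run of consecutive samples with p < 0.05 *and*
constant t sign, reported when at least 10 samples long (≈19.5 ms at
512 Hz). Requiring a constant sign is our choice: a sign flip marks a
reversal of the effect direction, and merging opposite-signed runs would
misstate a cluster's meaning. Zero-variance samples get t = 0, flagged and
never significant, so degenerate noiseless comparisons cannot produce
spurious infinite statistics. Channels are treated independently with no
cross-channel multiplicity control, mirroring the per-electrode procedure
this implements; the output is exploratory and should be read as such.
The consecutivity rule itself — rather than a label-shuffling permutation
null — is the implemented procedure, because that is the rule actually
described for these analyses; a permutation extension would be additive,
not a replacement.

## Split-plot repeated-measures ANOVA

`rm_anova()` handles crossed within-subject factors with an optional
between-subjects group of unequal sizes. Each within-involving effect is
tested by projecting the subject × cell matrix onto orthonormal contrasts
(Kronecker products of `contr.poly` columns) and fitting the effect-coded
between design, giving Type III sums of squares for the group factor —
the behavior of the commercial packages these analyses are usually run
in. The Greenhouse–Geisser epsilon is `(tr M)² / (c · tr M²)` on the
contrast-projected residual covariance, clamped to `[1/c, 1]` and exactly
1 when a factor has two levels. Because "corrected where appropriate" is
ambiguous, both uncorrected and corrected p-values are always reported
along with Mauchly's test, and partial η² satisfies
`F·df1 / (F·df1 + df2)` by construction (note that a printed F(2, 36)
with η² = .185 implies an error df of 72, i.e. (n−2)(k−1); the package
always reports the true error df). The implementation is verified in the
test suite against base R's `aov` Error-strata decomposition on balanced
designs (|ΔF| < 1e−8) and against `car::Anova`'s epsilon on unbalanced
ones, and its type-I error is calibrated over 2000 null simulations.

Pairwise comparisons multiply raw p by the number of pairs (capped at 1)
and report pooled-SD Cohen's d for both paired and independent contrasts;
difference-SD d values are not recoverable from typical printed summaries,
so the pooled flavor is used consistently.

## The synthetic-session generator

The generator exists so that every downstream stage has known ground
truth. Its defaults are the task protocol values: 180 trials per block
with 20% NoGo (placed as an exact 36-of-180 count by default, for
deterministic tests; a Bernoulli mode exists), 400 ms stimuli, 200–400 ms
uniform ISI, lognormal reaction times. Gait blocks draw per-stride times
and lengths and per-step widths from normal distributions at configured
means and CVs (defaults near adolescent treadmill values: 1.3 s,
1237 mm, 196 mm, CVs 3/3/9%), build the AP trajectory as a
piecewise-linear stance descent plus half-cosine swing return — so each
stride has a unique maximum and minimum and detector ground truth is
well defined — and retain every draw and true event index as attributes.
ERP epochs are sums of Gaussian-in-time, Gaussian-on-scalp component
templates (polarity enforced: N2 negative, P2/P3 positive) plus lag-1
autoregressive noise, independent across channels: the simplest noise
that exercises the run-length behavior of the cluster statistic.

What the generator does *not* emulate: movement and ocular artifacts,
volume-conducted correlated noise, electrode drift, RT-locked component
latency coupling, or optic-flow-specific visual responses (conditions
enter only as labels and amplitude multipliers). Passing tests therefore
demonstrate that the estimators recover known parameters under idealized
noise — not that they are robust to every failure mode of real
recordings.

The two-group demonstration study (`simulate_erp_study()`) uses 12
participants per group, three task conditions, 24 trials per cell, 6 µV
AR(0.9) trial noise, 10% between-participant gain SD, and a CR-specific
P3 boost that is larger in the TD group and attenuated under walking
(TD 4.0/2.2/2.4 µV, ASD 1.5/1.8/1.8 µV for standing/walking/walking+flow).
These sizes keep a full run under a minute while leaving the paired
within-group effects clearly detectable and the group difference
detectable only where the configured gap is large — the qualitative
pattern of interest. Likewise, property tests use 200-stride gait blocks
and 2000-replicate null calibrations; these sizes were chosen once as a
balance between Monte-Carlo error and turnaround.

## Known limitations

- EEG file I/O covers delimited channel matrices with a locations file
  and YAML sidecar; EDF/BDF readers are not included.
- The cluster procedure controls multiplicity only through consecutivity,
  per electrode; no spatial clustering or permutation null.
- `rm_anova` requires complete within-subject designs; incomplete blocks
  must be handled (dropped or imputed) upstream.
- The spherical-head layout is idealized; no subject-specific
  digitization is supported.
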