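---
title: "Methods: jitter-surrogate response detection and fear-renewal statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jitter-surrogate response detection and fear-renewal statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optofear)
```

## What the package computes

`optofear` implements the two computational arms of a typical optogenetic
pathway-validation study: (1) deciding which prefrontal units respond to
20 Hz light stimulation of channelrhodopsin-expressing axon terminals, with
a jitter-surrogate significance test whose chance level is calibrated by
inter-spike-interval (ISI) shuffling; and (2) the statistics of
context-dependent fear-renewal behavior — stage aggregation of percent
freezing, an extinction criterion, planned unpaired t-tests at the
stimulation timepoints, and pooling of control groups.

Because every stage runs on synthetic data with known ground truth, the
pipeline can be exercised and validated end to end without any recordings.

## The responsiveness test

For each unit, spikes are binned at 1 ms relative to every pulse onset,
pooled over all pulses (trains of all durations and both light intensities
are pooled; short-latency responses do not differ qualitatively across
them). The null hypothesis — no fine-timescale locking to the pulse — is
represented by surrogate datasets in which every spike is displaced by an
independent random shift with magnitude uniform between 1 and 10 ms. One
hundred surrogate histograms are computed with identical binning; a bin is
significant when the observed count strictly exceeds the nearest-rank 99th
percentile of that bin's 100 surrogate counts, and a unit is called
responsive when at least one bin within 12 ms of pulse onset is
significant. The 12-ms window covers both onset-locked monosynaptic firing
(expected within ~2 ms) and rebound firing just after the 10-ms pulse
offset.

Responsive units are typed by the latency of the earliest significant bin:
before pulse offset means `excited`; at or after offset *and* with a mean
within-pulse rate below the pre-onset baseline rate means
`inhibited_rebound` (suppression during the pulse released at offset);
late excitation without suppression stays `excited`.

Design choices worth spelling out:

* **Jitter sign.** A literal one-sided reading ("adding a shift of 1–10
  ms") displaces the null histogram systematically rightward. The default
  draws the sign at random (`jitter_sign = "symmetric"`), the statistically
  neutral choice; `jitter_sign = "positive"` reproduces the one-sided
  variant. Both are tested; both detect injected responses.
* **Which spikes are jittered.** All of them. Only spikes within a maximal
  displacement of a test window can change the histogram, so the
  implementation displaces exactly those — the counts are identical, and
  the surrogate train always conserves the spike count.
* **Percentile and ties.** Nearest-rank percentile (the 99th order
  statistic of 100 surrogates) with strict exceedance: a tie with the
  threshold is not significant. This is the conservative direction for
  discrete counts.
* **No multiple-comparison correction across the 12 bins.** This is
  faithful to the planned analysis; its consequence is a substantially
  non-trivial per-unit chance level, which is *measured*, not assumed
  (next section).

## Chance calibration by ISI shuffling

Twelve uncorrected bin tests at a nominal 1% each, combined with the fact
that a displaced spike can never stay in its own 1-ms bin (the minimum
shift is 1 ms), give the detector a per-unit false-positive rate on
stationary data of roughly 15–20%. This is a property of the method, not a
bug in the implementation, and the pipeline treats it the way the original
analysis logic does: the detector's chance level is estimated empirically
by destroying stimulus alignment while preserving each unit's firing
statistics. For each unit, the order of its inter-spike intervals is
randomly permuted — keeping the spike count, the first and last spike
times, and the entire ISI distribution (hence rate and burstiness) exactly
— and the identical jitter analysis is re-run on the shuffled population.
The responsive fraction of each shuffle replicate forms the chance
distribution against which the observed fraction is judged; per-site
observed-vs-chance pairs are compared with an exact Wilcoxon signed-rank
test (`signrank_compare()`, which keeps an exact permutation null under
tied differences — routine when the paired values are proportions over a
handful of sites).

Consequently the package's population summary reports, alongside the raw
responsive fraction, the *excess over chance* (observed minus mean chance
fraction): with ~12% of units truly responsive this chance-corrected
fraction recovers the ground-truth rate to within a few percentage points,
while the raw fraction sits at truth plus the chance level, as it must.

## The synthetic-data generator

The generator reproduces the study conditions: per trial a 5-min baseline
followed by 20 Hz trains of 0.5, 1, 5 and 15 s (10/20/100/300 = 430
pulses), once each in random order, 30 s apart. The pulse width is 10 ms,
inferred from the pulse-offset rationale of the 12-ms window. Background
spiking is a gamma-renewal process (shape 1 = Poisson by default; shape
below 1 gives bursty trains); per-unit rates are drawn uniformly from 2–8
Hz, a plausible range for cortical units under urethane. Responses are
injected with per-pulse probability 0.3: excited units gain one spike at
1.5 ms latency with 0.2-ms truncated-Gaussian latency noise (so the
response stays mostly within one 1-ms bin, mimicking sharp monosynaptic
peaks); inhibited-rebound units lose background spikes within the pulse
(suppression factor 0.2) and gain a rebound spike uniformly within 2 ms of
pulse offset, inside the 12-ms test window. Population class fractions
default to 8% excited + 4% inhibited, the ~12% responsive rate.

Freezing tables are Normal(stage mean, SD 10)-then-clipped to [0, 100] per
animal and stage — simpler than a beta model and adequate for t-test
structure, since only group means and variances enter the planned
comparisons. Group sizes default to 10 stimulated animals and 9 + 9
controls; the two control groups share stage means exactly (the regime in
which pooling them is legitimate), and stimulated animals at laser-on
stages are shifted down by 20 points (an effect size of d = 2 at SD 10).

What the generator deliberately does not emulate: slow non-stationarities
(anesthesia state drift, up/down states), spike-sorting contamination and
unit loss, correlations between simultaneously recorded units, session
effects and animal-level random effects in the freezing data, and floor
compression of freezing percentages near 0/100 beyond simple clipping.
Passing tests therefore demonstrate correctness and calibration of the
*procedures*, not robustness of the science to those real-data features —
state drift, for instance, is precisely what the ISI shuffle is meant to
absorb on real data, and only partly can.

## Behavioral statistics

Stage values are per-animal means over raw epochs (e.g. "CS 1–4" = mean of
the first four CS presentations). The extinction criterion is strict:
training continues until the CS 1–4 mean drops below 60%, and animals not
reaching criterion by day 7 are excluded. Group comparisons use Student's
pooled-variance unpaired t-test — forced by the published degrees of
freedom (groups of 7 + 7 reported with df = 12) — applied uniformly, with
`t_to_p()` converting any (t, df) pair to its two-sided p. The two control
groups are pooled only when no shared stage differs at p < 0.05
(`pool_controls_check()`); timecourse comparisons of stimulated vs pooled
controls are uncorrected by default (planned comparisons at the
stimulation timepoints; the design choice that maximizes sensitivity), with
Holm or Bonferroni adjustment available and reported alongside raw
p-values when requested.

## Numerical choices and degenerate inputs

* Half-open bins throughout, with a 1e-9 guard when flooring relative
  times, so edge-exact constructed spikes bin predictably.
* Zero baseline variance in z-scoring gives z = 0 with a `flat_baseline`
  flag rather than NaN; zero pooled variance in a t-test gives t = 0,
  p = 1 for equal means and an explicit error otherwise.
* Empty trains are legal everywhere (a silent unit is simply not
  responsive); an empty pulse list is an error (nothing to align to).
* ISI shuffling of trains with fewer than 3 spikes returns them unchanged.
* All randomness flows from one master seed through `child_seed()` (a
  Lehmer-style map into the 32-bit range), so each shuffle replicate,
  surrogate set and simulated unit is reproducible in isolation and whole
  runs are byte-identical under a fixed seed.

## Problem sizes used in the shipped checks

The validation suite exercises: specificity on 1000 stationary 5-Hz
Poisson units against a 39-replicate ISI-shuffle chance band; recovery on
two independent 2000-unit populations (one serving as a labeled oracle for
sensitivity and false-positive rate, one as the test set); per-bin
surrogate coverage on 200 null units; 1000 null and 300 effect replicates
of the behavioral arm; and exact invariants (ISI multiset preservation,
signed-rank enumeration) on 100-train batches. The acceptance script
recomputes the same quantities at 600/1600-unit and 500-replicate sizes.
These sizes give standard errors comfortably inside the tolerances being
checked while keeping a full run in the minutes range on one core.

## Known limitations

* The detector's absolute chance level depends on firing rate and
  burstiness; comparisons should always be made against the ISI-shuffle
  estimate computed on the same units, never against a nominal 1%.
* Typing uses only the earliest significant bin plus a mean-rate
  suppression check; it does not estimate latency beyond the first
  significant bin and can mistype units with mixed excitation/suppression.
* The behavioral arm models stage-level percentages only; it does not
  ingest raw video scoring or infrared beam breaks, and session-level
  trends within a stage are out of scope.
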