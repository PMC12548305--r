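# optofear

Spike-train and behavioral statistics for optogenetic pathway-validation
experiments: detection of light-evoked responses in prefrontal units with a
jitter-surrogate test calibrated by inter-spike-interval (ISI) shuffling,
and the planned group comparisons of context-dependent fear-renewal
behavior. A synthetic-data module generates stimulation protocols, spike
populations with known ground truth, and freezing tables, so the whole
pipeline runs and is validated without any recorded data.

It is written for electrophysiologists and behavioral neuroscientists who
stimulate axon terminals (e.g. ventral-hippocampal afferents to prelimbic
cortex) with 20 Hz light-pulse trains and need to answer two questions:
*which recorded units respond to the stimulation, beyond what the detector
would call responsive by chance?* and *does stimulation during specific
behavioral stages change freezing, relative to pooled controls?*

## The statistics at the core

**Responsiveness.** For unit $i$ with spike times $\{t_k\}$ and pulse
onsets $\{s_j\}$, spikes are binned at 1 ms relative to onset, pooled over
pulses. Surrogate datasets displace every spike by an independent shift
$t_k \mapsto t_k + \epsilon_k$, $|\epsilon_k| \sim U(1, 10)$ ms (sign
random by default), and the histogram is recomputed for each of 100
surrogates. A bin is significant when its observed count strictly exceeds
the nearest-rank 99th percentile of its surrogate counts; a unit is
responsive when any bin in $[0, 12)$ ms is significant — covering
onset-locked monosynaptic firing (~2 ms) and rebound just after the 10-ms
pulse offset. Responses are typed `excited` (earliest significant bin
before pulse offset) or `inhibited_rebound` (earliest bin at/after offset
with within-pulse rate below baseline).

**Chance calibration.** Twelve uncorrected 1-ms bin tests give the
detector a non-trivial per-unit false-positive rate (~15–20% on stationary
data). The pipeline measures it rather than assuming it: each unit's ISI
order is randomly permuted (preserving spike count, first/last spike time,
and the full ISI distribution — hence rate and burst structure — while
destroying stimulus alignment), the identical jitter analysis is re-run,
and the observed responsive fraction is compared to the shuffle
distribution; per-site pairs go into an exact Wilcoxon signed-rank test.
The population summary reports the excess over chance, which recovers a
ground-truth ~12% responsive rate within a few percentage points.

**Behavior.** Per-animal stage means (e.g. CS 1–4), a strict extinction
criterion (mean freezing over the first four CS presentations < 60% within
7 daily sessions), Student pooled-variance unpaired t-tests
($\mathrm{df} = n_1 + n_2 - 2$) at the planned stimulation timepoints, and
pooling of the two control groups only when no shared stage differs at
p < 0.05.

## Worked example

```r
library(optofear)

protocol <- gen_protocol(seed = 1)          # 5-min baseline, 20 Hz trains of 0.5/1/5/15 s
protocol
#> <stim_protocol> 430 pulses @ 20 Hz (width 10 ms), 4 trains of 0.5/1/5/15 s, baseline 300 s, total 441.5 s

pop   <- gen_population(60, frac_excited = 0.08, frac_inhibited = 0.04,
                        protocol, seed = 2)
calls <- detect_population(pop$trains, protocol, seed = 3)
calls[[18]]                                  # a ground-truth excited unit
#> <response_call> unit 'u018': responsive (excited; significant bins at 1 ms)

summarize_population(calls)[c("responsive", "total", "fraction")]
#> $responsive
#> [1] 17
#> $total
#> [1] 60
#> $fraction
#> [1] 0.2833333

sr <- chance_fraction(pop$trains, protocol, n_shuffles = 10, seed = 4)
sr
#> <shuffle_result> site 'site1': observed fraction 0.267, chance 0.212 +/- 0.039 (10 shuffles, 60 units)
```

The raw responsive fraction (28%) is the true rate *plus* the detector's
chance level; the chance estimate on the same units (21%) makes that
explicit, and the excess over chance (~6% here, noisy at 60 units; the
shipped tests use 1000–2000 units where it recovers 12% within 3
percentage points) is the calibrated quantity to report.

```r
tbl <- gen_freezing_dataset(freezing_spec(seed = 4), "ABA")
pc  <- pool_controls_check(tbl)              # controls indistinguishable -> pooled
timecourse_compare(pc$table)[, c("stage", "n1", "n2", "mean1", "mean2", "t", "df", "p")]
#>              stage n1 n2 mean1 mean2      t df       p
#> 1     conditioning 10 18  60.0  60.5 -0.136 26 0.89325
#> 2 extinction_first 10 18  72.7  74.2 -0.324 26 0.74870
#> 3  extinction_last 10 18  40.4  38.9  0.453 26 0.65398
#> 4   baseline_laser 10 18  38.2  56.0 -3.698 26 0.00102
#> 5               CS 10 18  50.8  53.0 -0.516 26 0.61026

t_to_p(2.51, 12); t_to_p(2.80, 24)           # printed (t, df) pairs -> two-sided p
#> [1] 0.02718975
#> [1] 0.009971864
```

Only the laser-on baseline stage differs between stimulated animals and
pooled controls — the generator's built-in 20-point freezing reduction —
while conditioning, extinction and CS stages do not.

A command-line wrapper with `simulate-ephys`, `simulate-behavior`, `peth`,
`detect`, `calibrate`, `behavior` and `report` subcommands is installed at
`system.file("cli", "optofear.R", package = "optofear")`; every run writes
a manifest with its master seed, and repeated runs are byte-identical.

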