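---
title: "Models and methods: auditory-cortex speech-discrimination metrics on synthetic spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`aafdiscrim` implements the standard analysis chain for multiunit
recordings from the rat anterior auditory field (AAF) in a
prenatal-valproate (VPA) autism model, before and after go/no-go speech
training: peristimulus time histograms (PSTHs) and the three
speech-response metrics (driven spike count, onset latency, peak latency),
a single-sweep PSTH nearest-neighbor classifier for pairwise consonant
discrimination, vector strength for 10 Hz noise-burst trains, tone
frequency–intensity tuning curves (CF, threshold, BW40), and behavioral
scoring (percent correct, d′, stage criteria). Because no recordings are
deposited with the source study, the package pairs every analysis with a
synthetic-cortex generator whose four group presets (VPA untrained, VPA
speech-trained, saline untrained, saline speech-trained) are calibrated so
the full analysis chain reproduces the reference group means.

## Data model

Spike times are milliseconds, floating point, 0-based relative to sweep
start, with the stimulus onset carried explicitly per `sweep_set` — every
metric is onset-relative, so nothing depends on an implicit sweep layout.
Empty sweeps are first-class: a silent sweep still counts in every PSTH
denominator. The on-disk dialect is one CSV row per spike with the sweep
window and onset as columns and an `NA`-time row preserving silent sweeps;
this keeps fixtures diff-able and the repository free of binary
electrophysiology containers. Sweep duration is never assumed: the window
travels with the data.

## Response metrics

**PSTH.** Half-open 1-ms bins (a spike exactly on the right window edge is
excluded), counts summed over sweeps, rate = counts / (n_sweeps × width).

**Driven spikes.** Mean spikes per sweep in the 40-ms post-onset window
minus the spontaneous expectation for 40 ms. The baseline is estimated from
the 100 ms immediately pre-onset of the same site (the source methods do
not define the baseline window; 100 ms is the package default and is
configurable). Subtraction makes the metric invariant to the spontaneous
rate; the raw evoked count is available via `subtract_baseline = FALSE`.
The same 40-ms convention is applied to all 11 words.

**Onset latency.** Start time of the first post-onset bin whose rate
strictly exceeds baseline mean + 3 baseline SDs, with baseline statistics
taken across the pre-onset bins of the trial-summed PSTH. When the baseline
SD is zero the rule degenerates to any strictly positive excess over the
baseline mean. If no bin crosses within the 100-ms search window
(configurable; the source is silent on the search span) the latency is
undefined (`NA`) and excluded from group means — an undefined latency is
not a latency of zero. Onset latency reports the bin *start*
(threshold-crossing semantics); peak latency reports the bin *center*
(argmax semantics), ties toward the earliest bin.

A first-crossing detector on a Poisson baseline has an irreducible
false-crossing rate: at a 3-SD threshold each pre-response bin crosses with
probability ~0.3–1% regardless of the baseline rate, so across many
sites a small fraction of latencies land early on baseline noise. The
latency-recovery tests therefore assert that at least 45 of 50 random step
latencies are recovered within one bin (all 50, when the baseline rate is
zero), rather than pretending the estimator is infallible.

## Single-sweep classifier

Each sweep is reduced to 40 spike counts (1-ms bins over the 40-ms onset
window). A stimulus's template is the per-bin mean across its sweeps; a
single sweep is assigned to the template at smaller Euclidean distance,
ties deterministically to the first label. Templates are leave-one-out by
default — the source text compares single trials to "the average activity
pattern" without stating whether the test trial is excluded, and LOO avoids
resubstitution optimism; `loo = FALSE` reproduces the literal reading. The
per-site accuracy is the unweighted mean over the 21 unordered pairs of
the seven same-vowel consonant words; groups average across sites.

Two properties of this estimator matter for testing. First, with one
shared random template pair, the per-sweep assignments are *correlated*, so
a single experiment's percent correct on identically distributed stimuli
has variance well above binomial; chance-level checks pool sweeps across
independent sites. Second, LOO on identically distributed data is slightly
pessimistic (the excluded sweep pulls its own template away), which the
tests verify directly against resubstitution.

## Vector strength

For spikes pooled across sweeps and referenced to the first burst onset,
θᵢ = 2π tᵢ / T and VS = √(Σcos θᵢ)² + (Σsin θᵢ)² / n. The analysis window
runs from the first burst onset to the last onset + T; spikes before the
first burst are excluded. Zero spikes give an *undefined* VS (excluded from
group means) rather than 0, which would fabricate asynchrony. For Gaussian
spike-timing jitter of SD σ the phase distribution is wrapped normal and
E[VS] = exp(−2π²σ²/T²) — the closed form every synchronization test is
anchored to. The per-burst peak rate is the maximum 1-ms-bin rate within
each burst's [onset, onset + T) span, averaged over the six bursts.

## Tuning curves

A lattice point "evoked a response" when its mean count over sweeps
exceeds the spontaneous mean by 2 per-sweep spontaneous SDs (the source
never operationalizes "evoked a response"; the 2-SD criterion is the
package's definition and is configurable). The per-sweep SD — not the
standard error of the point mean — keeps the criterion stringent across
the 41 × 16 lattice; a standard-error criterion of the same nominal level
floods the mask with false positives at the lowest intensities and
collapses measured thresholds. CF is the frequency responsive at the
lowest responsive intensity (ties: larger count, then lower frequency);
threshold is the lowest responsive intensity at CF; BW40 is log₂(f_max /
f_min) over the contiguous responsive span containing CF at the row
nearest threshold + 40 dB (holes terminate the span; a loose min–max rule
is available). The rate–intensity function averages driven counts over
frequencies within ±1 octave of CF, clipped at grid edges. Tone counts use
the same 0–40 ms window as speech (source silent).

## Behavior

Percent correct is the unweighted average of the hit rate and the
correct-rejection rate, even for unbalanced trial counts (that is the
stated definition). d′ = z(hit) − z(false alarm) with extreme rates clamped
to 1/(2N); the log-linear alternative was rejected for simplicity. The
d′ ≥ 1.5 "for 10 sessions" stage rule is read as 10 *consecutive*
qualifying sessions (the source is ambiguous); a cumulative mode is behind
a flag. Learning curves align subjects by session index over 15 sessions
(three 5-day weeks) and report across-subject mean ± s.e.m.

## The synthetic cortex and its calibration

**Onset responses** are inhomogeneous Poisson processes: constant
spontaneous rate (20 Hz at the multiunit sites the presets emulate) plus a
Gaussian rate bump, sampled exactly by thinning. The bump is the simplest
form whose strength (peak), latency (center) and width (SD) map one-to-one
onto the three reported metrics. Each of the 11 words perturbs the bump
(center offsets spread over ±12 ms, peak fractions ±15%, identical across
groups) so the classifier has discriminable single-sweep patterns; the
offsets average to zero so group-level targets are unchanged. Site
heterogeneity — a multiplicative response gain (SD 0.4), a center jitter
(SD 3 ms), a burst-jitter deviation (SD 1.5 ms) — is set so that s.e.m.
at ~100 sites matches the reference s.e.m. magnitudes.

**Calibration is analytic, not fitted to simulations.** For each group the
bump peak comes from the closed-form Gaussian integral of the driven-count
target; the bump center is found by root-finding on an *expected
first-crossing* model of the latency detector, which combines the exact
per-bin Poisson crossing probabilities, the sampling distribution of the
integer count threshold implied by an estimated baseline (tabulated once;
the statistic's skew matters at baseline counts below ~1 per bin), and
quadrature over the site-gain and center-jitter distributions — the gain
integral needs a tail-resolving grid because latency is convex in gain.
The burst jitter inverts the wrapped-normal VS form averaged over site
jitter; the spikes-per-burst inverts the exact expectation of the PSTH
maximum (the reported peak rate is a maximum over ~100 Poisson bins and
overshoots the center-bin rate, which the calibration accounts for). With
100 sites × 20 sweeps the full pipeline reproduces every driven-spike,
onset-latency and VS target within two measured s.e.m., and the tone
thresholds and bandwidths land within ~1 dB / ~0.1 octave of their
targets.

The one deliberately unmet magnitude is the VPA-untrained classifier
accuracy: the reference prints ~70% versus ~74–75% for the other groups,
but under the shared template geometry a 1.3-driven-spike response cannot
support 70% single-sweep accuracy — the preset saturates near 60%. The
group *ordering* (VPA-untrained below both trained and control groups,
trained VPA ≈ saline) is reproduced and is what the package asserts.
Similarly, peak latencies preserve the reference ordering (VPA-untrained
slowest) but not the printed 17.8–24.2 ms span: with a symmetric bump and
the 3-SD rule at these signal-to-noise ratios, the onset-to-peak gap
cannot be both ~3.7 ms (trained) and ~7.3 ms (untrained) at the calibrated
onset latencies. Onset latency, the primary latency target, is calibrated;
peak latency follows the bump center.

**Trains** place Poisson(spikes/burst) spikes at each of six burst onsets
(10 Hz) with Gaussian jitter. **Receptive fields** are upward-opening Vs:
responsive where intensity exceeds threshold + (80 / BW40) × |octaves from
CF|, with driven counts rising linearly above the local threshold (2.5
spikes at threshold, 0.05/dB) — strong enough that the 2-SD criterion
detects the field edge at the programmed rows. A noiseless grid
constructor exposes the exact expected counts for grid-exact recovery
tests. **Behavior** draws each trial from an equal-variance
signal-detection model with hit = Φ(d′/2 − c), false alarm = Φ(−d′/2 − c),
neutral criterion, 50/50 target ratio (the source does not state the
ratio; both are configurable), and a saturating d′ trajectory
d′(s) = a(1 − e^{−s/3}) with consonant-task asymptotes 1.2 (VPA) vs 1.8
(saline) and equal vowel-task asymptotes — the qualitative structure of
the behavioral result.

**Reproducibility.** One master integer seed drives a hierarchical stream
(site → stimulus → sweep) via multiplicative folding, so any subset of a
dataset regenerates bit-identically; all generators are deterministic
given the seed.

## What the synthetic data do and do not show

The generator emulates onset-locked multiunit responses with independent
Poisson variability, stationary baselines, symmetric latency jitter and
independent sites. It does not model adaptation across the burst train,
correlated trial-to-trial excitability, non-Poisson bursting,
cortical topography, or any acoustic structure of the vocoded words —
per-word templates are abstract bump perturbations, not acoustics. Passing
tests therefore certify the *analysis chain* (definitions, estimators,
pipelines) and the generator's statistical contracts; they do not certify
that the estimators are unbiased on real cortical data with those
unmodeled features.

## Numerical choices and degenerate inputs

Half-open bins everywhere, with a guard for floating-point round-up at the
right edge; V-flank membership uses a 1e-9 dB tolerance so lattice points
exactly on the flank stay inside the field; classifier ties go to the
first label; argmax ties to the earliest bin; zero-spike VS and
no-crossing latencies are `NA` and excluded from means, never zero-filled;
d′ is clamped finite via 1/(2N); `evaluate_stage` of an empty session
sequence is "not yet". Group inference is delegated to Welch's t-test
(the source's repeated-measures ANOVA on behavior is descriptive here, not
re-implemented), with a Bonferroni factor of 16 for the intensity-sweep
family (0.05/16 = 0.003125).

## Problem sizes

The shipped configuration mirrors the reference design: 20 sweeps per
stimulus, ~100 sites per group, 11 words, a 41 × 16 tone lattice, 10
subjects × 15 sessions × 100 trials. The test suite runs the full
four-group pipeline at 100 sites × 20 sweeps and the remaining checks at
the smallest sizes that make their statistics decisive (e.g. 200 sweeps
for VS recovery at ±0.01, 2000 sweeps for driven-count recovery at ±0.08,
800 pooled sweeps for chance-level classification).
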