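---
title: "Models and methods: place-cell sequence analysis on the detour maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: place-cell sequence analysis on the detour maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `placeseq`, the
assumptions behind them, the tunable parameters with their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the methods literature leaves the design open.

## The experimental structure being modeled

The package targets recordings from a square track maze of four connected
150 cm linear tracks (T1–T4), where on some sessions the removable middle
50 cm of one track (the *mobile* segment) is replaced by a 150 cm U-shaped
*detour* segment, and later restored (*reversal*). A recording day
alternates sleep and run sessions (Sleep1, Run1, …, Run4). All analyses
work in a session-relative time base (seconds, float64) and a concatenated
linear maze coordinate (cm), with explicit per-track offsets stored in
`maze_config()`. Position samples are snapped perpendicularly onto the
nearest track polyline; samples farther than a tolerance (default 10 cm)
from every track are flagged invalid and excluded rather than clamped,
since clamping would fabricate occupancy at track edges. Corner ties go to
the lower-indexed track, which keeps linearization deterministic.

## Place maps and remapping

Place maps are spike counts over 2 cm bins divided by occupancy, both
computed from samples with speed > 10 cm/s; counts and occupancy are
smoothed *separately* with a Gaussian kernel (sd 2 cm) and then divided,
which avoids the edge bias of smoothing the ratio. Bins with under 0.1 s
of raw occupancy are masked. Spatial information is
`Σ p_b (f_b/F) log2(f_b/F)` in bits/spike. Within-session stability is the
mean cosine similarity of maps from 100 random lap bipartitions; because a
single lap rarely accumulates 0.1 s per 2 cm bin, per-lap maps are built
unmasked (the mask is a session-level concept).

Remapping between segments is assessed per unit as the Pearson correlation
of the two segment maps, maximized over shifts of up to 2 bins (4 cm), for
units with peak rate above 2 Hz on at least one segment, against a
1000-fold cell-identity shuffle. When a 150 cm segment is compared with a
50 cm one under the stretch hypothesis, the longer segment is rebinned to
6 cm (`rebin_maps`) so bin counts match. Ensemble-level comparisons use
population-vector cosine similarity per spatial bin, and sequence-level
comparisons use the Spearman correlation of peak-location orderings.
Bidirectionality of a unit is the cosine similarity of its two directional
maps — the literature reports bidirectionality without a formula, and
cosine similarity is the natural ensemble-consistent choice.

## Offline frames, theta phase, brain states

Frames are detected from pyramidal multi-unit activity binned at 1 ms and
smoothed with a 15 ms (sd) Gaussian kernel: excursions above mean + 2 sd
are extended outward to the mean crossing, then filtered to 100–1200 ms,
at least 5 distinct units, and immobility (< 2 cm/s) throughout. The MUA
mean and sd are computed over immobility periods of the session — this is
where the method's operating point lives: in recordings the burst frames
themselves dominate the MUA variance, which lifts the threshold well above
the level of Poisson background fluctuations. On a *flat* Poisson
background with no burst structure, mean + 2 sd of the smoothed trace is a
low bar and the detector emits excursion-rate-limited false positives (the
test suite checks this rate against the analytic Gaussian-excursion
oracle); at realistic frame densities (the package default injects 20
frames/min) the false positives are negligible. Note also that the Gaussian
kernel widens every burst by roughly ±2 kernel widths before the mean
crossing, so the 100 ms duration floor acts on bursts shorter than ~40 ms,
not on everything under 100 ms.

Theta phase comes from a zero-phase (forward–backward) order-4 Butterworth
band-pass at 7–10 Hz followed by the FFT analytic signal; phase 0 is the
filtered-LFP peak and the trough sits at 180°. Cycles are the intervals
between consecutive phase peaks; durations outside 0.9/10–1.1/7 s are
flagged out-of-band. Ripples are 140–220 Hz power-envelope events
(> mean + 5 sd, extended to mean + 2 sd, 30–200 ms), with a 2 ms envelope
smoothing chosen so that the envelope of a 160 Hz burst is resolved
without smearing sub-30 ms events past the duration floor. The theta brain
state requires speed > 10 cm/s and a (7–10 Hz)/(2–15 Hz) power ratio above
its session median — by construction this flags about half of a session
that is uniformly theta, and becomes a sharp classifier only when the
session mixes states, which is the intended regime.

## Decoding and trajectory scores

The decoder is the standard memoryless Poisson population decoder with a
uniform spatial prior, accumulated in log space (results invariant to unit
evaluation order to 1e-10). Template rates are floored at
`rate + mean_rate × 1e-5` so no spatial bin has zero likelihood. Time bins
are 20 ms for frames and theta cycles, 40 ms for run-time context
decoding, 200 ms for decoder validation against the animal's true
position. Zero-spike bins decode to the prior and are flagged. In
concatenated decoding, per-track templates are rescaled to a common mean
rate before normalization across the union — otherwise high-rate templates
absorb probability whenever spikes are plentiful (a bias the test suite
demonstrates and the rescaling removes).

A decoded frame is scored by the posterior-weighted Pearson correlation
between time and position (wc) and the maximum jump of the per-bin
posterior peak normalized by track length. Significance uses random
permutation of time-bin columns (a circular-shift variant is exposed as an
option); the two-parameter criterion is |wc| > 0.6 and jump < 0.4, both
configurable. Frames are decoded on their spiking bins; the replay
direction of a significant frame is the sign of wc on the best-|wc|
template, ties broken toward the lower template index.

## Theta sequences and their controls

Cycle posteriors are recentered on the animal's position at the cycle
midpoint, the spatial axis oriented along the running direction, and
restricted to ±40 cm. The quadrant ratio sums posterior mass in the
(ahead, late) and (behind, early) quadrants minus the other two, over the
total; the temporal split is the cycle's midpoint. Cycles are scored only
in the theta state with more than 3 active units (the drift-prediction
variant uses more than 4, matching its own convention; both are
parameters). Population significance is a one-sided signed-rank test for
positive QR.

Two caveats that the synthetic experiments make explicit. First, with the
animal moving, the decoded position advances within a cycle simply because
the animal does: at 30 cm/s and 8 Hz this contributes a residual positive
QR of roughly 0.05–0.1 even with all phase coding removed. Spike-time
jitter therefore collapses the QR toward this behavioral floor rather than
to zero, and the jitter experiment is read as an effect-size collapse.
Second, phase precession is implemented in the generator as a preferred
phase advancing linearly with distance traveled *into* the field along the
current running direction — defining it in absolute maze coordinates
instead silently reverses the phase code on return laps and cancels the
population theta sequence, which is also why the precession regression
(linear Pearson of raw phase against normalized in-field position, not
unwrapped, per the method being reimplemented) must orient the in-field
coordinate by direction before pooling.

Pairwise temporal structure uses the cross-correlogram center of mass
within ±200 ms (theta-compressed) or ±1000 ms (behavioral), computed as
the mean lag so the antisymmetry `bias(i,j) = −bias(j,i)` is exact; CCG
curve similarity uses low-pass-filtered histograms with peaks required to
exceed mean + 2 sd and 2 counts. Because tuning on the maze is
bidirectional, pair order flips with running direction and biases are
computed per direction.

The matched-false-positive comparison between theta-sequence emergence and
waking-rest replay estimates the replay criterion's empirical
false-positive rate from time-bin shuffles of the candidate frames, caps
the theta-sequence alpha at that rate, and then, for each candidate frame,
tests the QR population of all earlier cycles — so both phenomena face the
same number of tests at matched error rates, and each gets a first
significant time and lap.

## Markov model, tuplets, order consistency

Frame sequences order each frame's units by spike-time center of mass
(ties by unit id, so sequences are deterministic). The first-order model
is the maximum-likelihood estimate: transition counts accumulated across
frames and normalized per predecessor; zero entries are clipped to the
matrix's smallest non-zero value and exact ones to the largest non-one
value, so a single unobserved transition cannot annihilate a long
sequence's probability. Sequence probabilities are accumulated in log
space and compared with same-length random sequences drawn uniformly
*without* within-sequence repeats, matching the one-appearance-per-unit
structure of the data sequences. Percentiles count strictly smaller
shuffle values, so a degenerate uniform model yields percentile 0 rather
than an arbitrary tie value. The reference analysis uses 500,000 shuffles
per sequence; the package defaults to 10,000 (percentile standard error
~0.5 at the 95th percentile, adequate for a 5% decision) and exposes the
count. The batch evaluator regenerates a fresh shuffle pool per chunk of
100 sequences per length; sharing a pool within a chunk leaves each
sequence compared against a full complement of random sequences while
keeping the evaluation vectorized.

Tuplets are contiguous 2- and 3-unit sub-sequences of the frame orderings
with at least two repeats (contiguity is a documented choice; the
non-contiguous variant is available), compared against 500 shuffled sleeps
that resample each frame's unit count weighted by overall participation —
preserving rates, destroying order and co-firing. A candidate is a tuplet
when its count exceeds its own 95th shuffle percentile. One regime caveat:
when frames are so few that candidate motifs have expected counts well
below one, the two-repeat candidate gate conditions on outliers and the
apparent significant fraction among 3-unit candidates inflates above 5%;
calibration holds when expected candidate counts are of order one or more,
which is the regime of real sleep (thousands of frames).

The pairwise order matrix gives `P(i before j)` among frames where both
fire, exactly antisymmetric by construction; cycles are scored by the mean
matrix entry over their observed ordered pairs minus the 0.5 chance level.
Frame–cycle rank-order correlation requires at least 5 common units
(120 independent orderings) and compares each Spearman correlation with
500 within-pair permutations.

## Plasticity, assemblies, drift

Tuning vectors concatenate the two 50 cm stationary segments so vector
length is configuration-independent; inclusion requires peak rate > 2 Hz
(and stability > 0.8 where session pairs are compared). The
plastic/elastic index and its ±0.3 classification cut follow the
drift/stable convention used for map correlations (the percentage reports
in the source analyses imply a cut without stating one; 0.3 keeps the two
conventions aligned). Session pairs are grouped by lag and detour relation
with virtual detour sessions assigned to the never-detoured tracks for
control comparisons.

Assemblies are eigenvectors of the correlation matrix of the z-scored
20 ms spike matrix with eigenvalues above `(1 + √(N/T))²`; members have
weights more than 2 sd above the eigenvector mean, and the sign is fixed
so the largest-magnitude weight is positive. Silent units are dropped with
a warning (their z-score is undefined). The Marchenko–Pastur bound is
asymptotic: the top noise eigenvalue fluctuates around the edge, and at
N = 20, T = 5000 pure-noise data crosses it in roughly 3% of seeds — the
calibration suite verifies ≥95% rejection over 100 seeds rather than
asserting an impossible 100%. Activation uses the outer-product projector
with zeroed diagonal, so single-unit firing contributes nothing.

Variance decomposition of post-detour tuning fits
`Post = c0 + c1·Ave + β1·Pre + β2·Det + β3·OT + β4·T1 + β5·T3` by ordinary
least squares over stacked (unit, bin) observations, with the `Ave`
regressor computed per direction. Each regressor's share is
`(resid_without − resid_full)/resid_full` on Frobenius-norm residuals —
nonnegative because the models are nested — with significance from a
1000-fold unit-identity shuffle of that regressor. Drift/stable prediction
splits Run4 units at a Run1–Run4 map correlation of 0.3, orders each group
by Run4 peak location per direction, and scores the resulting sequences
under the Sleep1 and Sleep3 transition models.

## Flickering

Run-time context decoding concatenates five mean-rate-rescaled templates
(first stationary, current, last stationary, alternative, control — the
control segment mirrored on the opposite side of the maze, configurable);
only bins with more than 3 active units feed downstream analyses, while
strong-representation bins additionally require probability > 0.9 with at
least 3 active units. Epochs are maximal runs of smoothed (40 ms moving
average) summed context probability above 0.5 at speed > 10 cm/s, with
boundary bins below threshold excluded; the threshold applies to the
smoothed trace since the smoothing is part of the epoch definition.
Phase curves use windows with 90% overlap, so the s.e.m. is computed with
degrees of freedom reduced to 10% of the window count; all epoch-level
statistics use non-overlapping bins. The lap-by-position pattern of
non-local probability is summarized by its first principal component with
loadings scaled by the component's sd (so a structureless matrix yields a
near-zero spatial profile) and oriented toward positive probability.

## The synthetic generator: what it does and does not emulate

`generate_run_session()` produces ping-pong laps over the maze at a mean
speed of 30 cm/s with ±25% slow sinusoidal speed variability, Gaussian
place fields (sd 10 cm, peak 15 Hz, baseline 0.1 Hz) shared between
directions, theta-modulated inhomogeneous-Poisson spiking (8 Hz, default
modulation depth 0.7) with phase precession (default −6.5°/cm from a 300°
onset, i.e. ~260° of precession across a field — full-cycle precession
would wrap the raw-phase regression at both field ends), and a
sinusoid-plus-noise LFP whose Hilbert phase is known exactly. The speed
variability matters: at perfectly constant speed, theta modulation and
position lock into standing interference fringes at wavelength v/f
(~3.75 cm) that displace empirical peak locations by 1–2 cm.

`generate_sleep_session()` injects 20 frames/min (the frame densities
reported for overnight CA1 sleep recordings imply 15–30/min) of ordered
motif bursts — ≥5 participating units, 30 ms unit lags, 5 ms jitter, 2
spikes per slot — over 0.5 Hz/unit Poisson background, a roughly 10× local
rate contrast. Truth tables carry every frame boundary and order.
`apply_remapping_plan()` relabels units plastic/elastic/stable/random with
fresh Gaussian maps; `inject_flicker()` re-draws spikes inside chosen
epochs from the units' tuning at a position mapped onto the alternative
segment, optionally locking epochs to theta peaks.

Not emulated: interneurons, realistic LFP beyond band content, REM/NREM
architecture, behavioral pauses and reward consumption, biophysical spike
waveforms, and any coupling between remapping and assembly structure.
Passing tests on this generator demonstrate that the estimators recover
the structure they target at realistic signal strengths and calibrate at
chance on nulls — not that real recordings satisfy the generator's
independence assumptions.

## Problem sizes and reproducibility

Every generator call takes a mandatory seed and identical seeds give
bit-identical sessions. The test suite runs on sessions of 10–30 laps and
a few hundred sleep frames; the calibration suite uses 10,000 synthetic
cycle posteriors with 1000 subpopulations of 1000 for the theta-sequence
false-positive rate, 2000 frames × 10,000 cycle orderings for the
order-probability chance level, and 2000 cycles × 10,000 random sequences
for the Markov null. The pipeline (`run_pipeline()`) writes every stage's
artifact as CSV stamped with a config hash and the seed, and a rerun with
the same seed is byte-identical.
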