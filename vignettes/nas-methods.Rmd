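---
title: "Neuronal activation sequences: model, statistics, and synthetic calibration"
author: "naseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal activation sequences: model, statistics, and synthetic calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naseq)
```

## The problem

During a delayed-navigation working-memory task a subject sees a cue, holds
the target location in memory through a delay, and then navigates to it.
Simultaneously recorded prefrontal units often fire one brief burst per
trial, and the *times* of those bursts — rather than sustained firing
rates — can tile the trial and differ systematically by remembered target.
`naseq` implements the full analysis chain for this *neuronal activation
sequence* (NAS) hypothesis: extract per-trial peak-time vectors, test
their trial-to-trial precision against shuffle nulls, find the
time-boundary cells that parcel the trial into internally defined epochs,
embed trials by sequence similarity, relate that geometry to the subject's
visuospatial trajectories, and compare timing-based and rate-based codes
with cross-validated decoders.

Real recordings of this kind are not freely redistributable, so the
package ships a synthetic-session generator with planted ground truth.
Every statistic in the package is validated by recovery, calibration, and
ordering experiments on those synthetic sessions.

## Sequence extraction

A unit's spike-density function (SDF) is the spike train convolved with a
Gaussian kernel of SD 100 ms, evaluated on a 1 ms grid over the analysis
window `[0, t_end)` (seconds from cue onset).  The kernel is truncated at
±5 SD and not renormalized at the window edges; spikes are assigned to
their nearest grid point (≤ 0.5 ms error).  The trial's sequence vector
`S` holds each included unit's *peak firing time* `t_n` — the grid time of
the SDF's global maximum, ties resolved to the earliest grid point.  An
all-zero SDF (no spikes that trial) yields a missing entry, and the unit
keeps its column so unit order is identical across trials.

Units enter the analysis when their session-mean rate (total
analysis-window spikes over total analysis time) is at least 0.5 Hz.  The
averaging window for this criterion is a package choice; it is the least
assumption-laden reading of a whole-session rate floor.

Densities are computed once over the whole trial and *masked* afterwards:
an epoch-specific sequence sets entries outside the half-open epoch window
`[start, end)` to missing.  All windows in the package are half-open, so
a peak exactly at a boundary belongs to the later epoch.

## Timing consistency

For every target condition with at least five trials, `peak_sd()` computes
the sample SD (n−1 denominator, appropriate at small per-condition trial
counts) of each unit's non-missing peak times.  The pooled distribution of
these SDs is compared with a shuffle null: within each trial, the
assignment of peak times to units is permuted (missing entries stay in
place), the SDs are recomputed, and the procedure is repeated (default
100 times) and pooled.  Within-trial permutation preserves each trial's
time marginal while destroying unit identity — precisely the structure the
statistic is meant to test.  A per-unit across-trial permutation is
available as `semantics = "across_trial"`.

The headline statistic is the difference of distribution means,

  `mean_difference = mean(SD_shuffled) − mean(SD_real)`,

reported in milliseconds, so that *positive* values mean more consistent
timing than chance.  `consistency_summary()` also reports the fraction of
units whose best-condition SD (their minimum across conditions) falls
below given thresholds (defaults 1000 and 1500 ms).

## Time-boundary cells and neural boundaries

A time-boundary cell fires at the same trial time regardless of target.
Operationally, the across-trial distribution of a unit's peak times is
estimated by a Gaussian KDE and summarized by its full width at half
maximum (FWHM): the width of the contiguous region around the global mode
where the density stays above half its maximum (crossings located by
linear interpolation).  Units with FWHM below 1 s are labeled
time-selective.

`unit_fwhm()` defaults to a 0.1 s bandwidth, matching its closed-form
behavior (a point mass has FWHM `2.355 × bandwidth`).  The
*classification* stage (`boundary_analysis()`) instead smooths at 0.3 s —
the scale of the firing bump — for a structural reason: when
within-condition timing is precise, a narrow bandwidth resolves each of a
target-dependent cell's nine condition peaks as its own mode, and the
width of the tallest mode alone can mimic a time-locked cell.  Smoothing
at the bump scale merges condition structure into one broad lump (FWHM
well above threshold) while a genuine boundary cell — whose total spread
is jitter only — stays far below it.  With this choice the fraction of
selected units on synthetic sessions matches the planted boundary-cell
fraction within binomial error.

Pooling the peak times of all time-selective units over trials gives a
histogram (100 ms bins, half-open) with two anticipatory peaks.  The
tallest bin before delay onset and the tallest bin between delay and
navigation onset are the *neural boundaries* (bin centers).  Either can be
missing — as in a perception-guided control without anticipation — in
which case downstream epoch masking falls back to task boundaries with a
warning.  Boundary estimates use peak *locations*, so they are invariant
to the number of boundary cells.

## Spectral embedding

Sequence vectors `S_i`, `S_j` are compared by Pearson correlation over the
components non-missing in both.  Pairs sharing fewer than `min_overlap`
(default 10) components, or undefined because one vector is constant on
the shared support, get the neutral value 0; the diagonal is forced to 1.
The resulting T × T matrix `X` is decomposed as `X = V Λ Vᵀ`, eigenpairs
ordered by decreasing |λ| (ties by original index), each eigenvector's
sign fixed so its largest-magnitude entry is positive (all downstream
quantities are sign-invariant).  With `Q` the first k = 3 eigenvectors,
the trial coordinates are `P = XQ`.  Per-target centroid positions are
coordinate means, and the 9 × 9 centroid distance matrix is normalized by
its maximum entry.

Two spots where the package makes an explicit choice the method
description leaves open: the missing-data policy in the Pearson step
(pairwise-complete with an overlap floor, neutral 0 below it) and the
normalization constant (the matrix maximum).  Both are exposed as
arguments.

Epoch decoding embeds the pooled set of cue-, delay-, and
navigation-masked copies of every trial and classifies the three epoch
labels.  Here the embedding dimension defaults to six, not three: the
pooled correlation matrix holds three nearly disconnected epoch blocks,
each with its own internal condition geometry, so the three block-mean
directions need not be the top three eigenvectors by modulus.  Two
dimensions per class span both the means and the leading within-block
structure; target-level analyses keep k = 3.

## Behavioral linkage

Movement paths live in arena coordinates (targets on a 3 × 3 grid spaced
290 units apart; travel time between adjacent targets 0.5 s at the fixed
speed).  A pinhole camera at the trial start position (avatar eye height,
facing the grid, 90° horizontal field of view, 1024 × 768 screen) maps
paths to screen coordinates; the engine's exact projection constants are
not published, so all camera parameters are configuration with these
defaults.  Screen paths are resampled to 50 points by arc length,
outliers excluded by the z > 1 rule on mean Frechet distance to the other
paths of the same target, and averaged pointwise.

Trajectory similarity uses the *discrete* Frechet distance (dynamic
programming over monotone couplings, Euclidean ground metric).  The
discrete variant is standard for sampled paths and admits an exact oracle:
the test suite checks the DP against exhaustive coupling enumeration on
hundreds of short random paths.

The link statistic is the Spearman rank correlation between the 36
upper-triangle entries of the centroid distance matrix and of the
trajectory Frechet matrix.  Its null is obtained by permuting target
labels across trials and recomputing centroids in the fixed embedding.
Alternative condition geometries — bird's-eye (world) trajectories,
optimal straight paths, raw target locations — plug into the same
statistic for comparison.  The ablation curve removes a random fraction of
units (entries set to missing), reruns correlation → projection →
centroids → ρ, and averages over iterations.

## Decoding

The unsupervised decoder assigns each test trial the label of the nearest
training-fold condition centroid (Euclidean distance, ties to the lowest
condition index), with stratified 5-fold cross-validation and analytic
chance 1/k verified empirically by label permutation.  Row and column are
decoded from the subsequences of row- and column-selective cells —
selectivity is the maximum pooled-SD Cohen's |d| between a unit's
spike-time distributions across condition pairs, thresholded at a
percentile tuned over a coarse grid (50/70/90) by cross-validated
accuracy — and the (row, column) prediction pair identifies one of nine
targets.

Persistent cells must (1) show target-tuned delay rates (one-way ANOVA
across the nine targets) and (2) elevate their preferred-target delay rate
above the inter-trial-interval baseline (one-sided Welch test), both at
the same p threshold; relaxing the threshold grows the set monotonically.
The rate-versus-timing comparison trains two linear maximum-margin
classifiers (stratified 10-fold): one on persistent-cell mean delay rates,
one on the sequence-projection coordinates of delay-epoch sequences.  The
task delay window is used for these features; analyses are insensitive to
the task-versus-neural boundary choice, and the task window keeps the
rate and timing features aligned on the same interval.

## The synthetic generator

`nas_config()` defaults describe one study-like session: 200 units, nine
targets × 20 trials, 3 s cue / 2 s delay / 1.5 s analyzed navigation /
2 s inter-trial interval, 1 Hz Poisson background, transient Gaussian
bumps with peak rate 25 Hz and SD 0.1647 s — calibrated so the width at
80% of maximum is 220 ms — trial-to-trial peak jitter of 100 ms, 5%
boundary cells anticipating delay and navigation onsets by 750 and
500 ms, and 20% + 20% row-/column-selective cells.  Spikes are drawn
exactly from the inhomogeneous Poisson process by superposition: counts
are Poisson with the integrated rate, times i.i.d. from the normalized
profile.  The same seed always reproduces the same session byte for byte,
with all draws in one documented order.

Three planting choices deserve explanation:

* **Epoch confinement.**  Each structured unit's nine per-target peaks
  stay within one task epoch, with a guard margin of about two bump SDs
  from the rate-analysis boundaries.  Without this, peaks that cross the
  delay boundary for some targets turn the timing code into a strong
  delay-*rate* code, and a session meant to carry only sequence structure
  would also be decodable from rates — exactly the confound the
  rate-versus-timing comparison must be able to separate.  Target cells
  occupy the cue or delay epoch (delay favoured 65:35, since the memory
  period carries the target code); row/column cells occupy cue or
  navigation.
* **Rank-based screen ordering.**  A target cell orders the nine targets
  by a random direction in *screen* space (the perspective-projected
  target layout, centred per axis and scaled by one common factor so the
  true anisotropy is preserved) plus idiosyncratic noise, then spaces its
  peaks evenly over a span of 1.4–2.2 s.  Even spacing guarantees the
  pooled peak distribution of a sequence cell can never collapse into a
  time-locked lump (so the FWHM classifier separates roles
  deterministically), while the ordering ties sequence geometry to the
  subject's viewpoint — the property the Spearman link statistic
  measures.  Rank rather than metric planting is sufficient because the
  link is itself a rank correlation.
* **Reflection at window edges.**  Planted peaks that would leave the
  trial window are folded back rather than clamped, avoiding artificial
  point masses at the edges.

Incorrect trials multiply the peak jitter (default ×2; the generative
mechanism behind error trials is unknown, so a single inflation dial is
the most parsimonious model) and end their trajectory off-target.
`mode = "persistent"` removes the timing code and gives every non-boundary
unit a preferred target with 10 Hz delay firing against a 2 Hz baseline;
`mode = "unstructured"` redraws every peak uniformly per trial with no
boundary cells; `mode = "perception_control"` is sequence mode without
boundary cells, mirroring a task that requires no anticipation.

**What the generator does not emulate:** real firing-rate heterogeneity
and burstiness, adaptation, correlated noise across units, multi-peaked
or epoch-spanning response profiles, eye movements, and behavioral
learning.  Passing recovery tests therefore shows the *pipeline* is
correct and calibrated under its stated assumptions — not that real
cortex contains planted Gaussian bumps.

## Experiment sizes and statistical reading of the checks

The validation experiments use deliberately chosen problem sizes:

* Chance calibration: ≥ 1000 embedded points with permuted labels;
  accuracy must sit within three binomial standard errors of 1/9 (target)
  and 1/3 (epoch).
* Recovery: one full-scale session (200 units, 20 trials/target, 100 ms
  jitter) for boundary offsets (±1 histogram bin), the link correlation
  (ρ > 0.8), and combined target decoding (≥ 80%).
* Null calibration: 20 unstructured sessions; the consistency mean
  difference is compared with a leave-one-out null over shuffle repeats,
  and ρ with its label-shuffle null.  With 40 nominal-95% draws, about
  two excursions are expected by construction, so the check bounds the
  violation count by the binomial 99.5% quantile rather than demanding
  every draw fall inside.
* Orderings: at full scale, centroid averaging makes ρ insensitive to
  pure jitter inflation, so the degradation experiments run in a
  sensitivity regime (40 units, 8 trials/target, 0.2 s base jitter,
  jitter ×3 on the 50% incorrect trials) where the statistic has room to
  fall; the consistency mean difference, which degrades at any scale, is
  checked at defaults.  The code-crossover experiments use 20 seeds per
  session mode with 5-fold classifiers (six trials per class).
* Ablation: the curve is averaged over 100 iterations × 3 seeds in the
  same sensitivity regime; adjacent fractions in the ceiling region
  differ by less than sampling noise, so monotonicity is asserted on the
  seed-averaged curve with a 0.01 tolerance.

## Numerical choices and degenerate inputs

Grid step 1 ms (well under the kernel SD); argmax ties to the earliest
grid point; empty spike trains give missing peaks, not errors; fewer than
two peaks give a missing SD or FWHM; a condition with no trials gives a
missing centroid row with a warning; constant distance matrices make the
rank correlation undefined and return 0 with a warning; all-outlier
trajectory groups fall back to no exclusion with a warning; an empty
persistent set marks the rate decoder as absent rather than failing.  All
randomness flows from explicit integer seeds, and the R session's RNG
state is saved and restored around every seeded computation.

## Known limitations

The FWHM of a multimodal distribution reflects only the tallest lobe;
role classification is reliable because the generator guarantees merged
lumps at the classification bandwidth, but on real data the bandwidth
matters and should be reported.  The Spearman link uses 36 matrix entries
and is correspondingly coarse.  The persistent-cell criteria assume
Poisson-like rate variability; strongly bursty units would need a
different test.  The camera model is a single static pinhole at the trial
start; a moving viewpoint would require per-sample extrinsics.
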