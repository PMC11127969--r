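# naseq — neuronal activation sequence analysis

`naseq` analyzes simultaneously recorded spike trains from
delayed-navigation working-memory tasks in which information appears to be
carried by the *timing* of brief firing bursts rather than by sustained
firing rates.  It is written for systems neuroscientists who want to test
a sequence-code hypothesis on session data (spike events, trial metadata,
3D movement trajectories) and for methodologists who want a fully
synthetic, ground-truthed testbed for such pipelines.

## The method

Each trial is represented by a vector of **peak firing times**
`S = (t_1, …, t_N)`, where `t_n` is the time at which unit *n*'s
spike-density function (spike train convolved with a Gaussian kernel,
SD = 100 ms) attains its maximum; entries outside an epoch of interest are
masked to `NA`.  On top of this representation the package provides:

* **Timing consistency** — per-(unit, condition) standard deviations of
  peak times (conditions with ≥ 5 trials) compared against a within-trial
  shuffle null; summarized by
  `mean_difference = mean(SD_shuffled) − mean(SD_real)` in ms.
* **Time-boundary cells** — units whose across-trial peak-time
  distribution has a full width at half maximum below 1 s fire at a fixed
  trial time regardless of target; the pooled histogram of their peak
  times defines anticipatory *neural boundaries* between task epochs.
* **Spectral embedding** — the T × T Pearson correlation matrix `X`
  between trial sequence vectors is projected onto its k = 3 leading
  eigenvectors by modulus, `P = XQ`; per-target centroids of `P` give a
  9 × 9 normalized distance matrix describing sequence discriminability.
* **Behavioral linkage** — movement paths are perspective-projected to the
  subject's screen view, averaged per target, and compared by discrete
  Fréchet distance; the Spearman correlation between the centroid and
  Fréchet distance matrices (36 upper-triangle entries) measures how
  closely sequence geometry tracks visuospatial behavior, with
  label-shuffle nulls and unit-ablation robustness curves.
* **Decoding** — unsupervised nearest-centroid cross-validated decoders
  for trial epoch (chance 1/3) and target (chance 1/9, directly or by
  combining row and column predictions from selective subpopulations),
  plus a rate-versus-timing comparison using linear SVMs on persistent-cell
  delay rates versus sequence-projection coordinates.
* **Synthetic sessions** — `simulate_session()` plants transient Gaussian
  firing bumps (width at 80% of max ≈ 220 ms) whose times tile the trial
  and follow the targets' screen-space geometry, boundary cells
  anticipating the delay and navigation onsets by 750/500 ms, optional
  persistent-rate and unstructured modes, and degraded (incorrect-trial)
  conditions — all deterministically from one seed.

## Worked example

```r
library(naseq)
cfg <- nas_config(n_units = 100, n_trials_per_target = 10, seed = 1)
session <- simulate_session(cfg)
session
#> <nas_session> 100 units, 90 trials, 169033 spikes
#>   synthetic (sequence mode, seed 1)

fit <- nas_fit(session, nas_control(stages = "decoding", seed = 1))
summary(fit)
#> Neuronal activation sequence analysis
#>   included units:      100 of 100
#>   trials:              90
#>   time-selective:      5 units (5.0%)
#>   neural boundaries:   pre-delay 2.25 s, pre-nav 4.45 s
#>   embedding:           k = 3, top |lambda| share = 0.47
#>   link rho:            0.785
#>   epoch decoding:      0.974 (chance 0.333)
#>   target decoding:     all-cell 0.978, combined 1.000 (chance 0.111)
```

Reading the output: 5 of 100 units are classified time-selective —
exactly the planted boundary-cell fraction — and their pooled peak times
place the neural boundaries 0.75 s before the delay onset (at 2.25 s) and
about 0.5 s before the navigation onset (at 4.45 s, within one 100 ms
histogram bin of the planted 4.5 s).  The memory-period sequence geometry
correlates with the screen-trajectory geometry at Spearman ρ = 0.79, and
both decoders sit far above their analytic chance levels, with combined
row × column decoding recovering every planted target in this session.
`plot(fit)` draws the trial embedding, the two distance matrices, and the
peak-time raster histogram.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/nas-pipeline.R", package = "naseq"))') \
    simulate --units 100 --trials-per-target 10 --seed 7 --out session_dir
# then: validate --in session_dir ; run --in session_dir --out results_dir
```

## Package layout

* `R/synth.R` — session generator and trajectories
* `R/sequences.R` — spike densities, peak times, sequence vectors
* `R/consistency.R` — timing-consistency statistics and shuffle nulls
* `R/boundaries.R` — FWHM, time-selective cells, neural boundaries
* `R/embedding.R` — correlation matrix, spectral projection, centroids
* `R/behavior.R` — camera, Fréchet distances, linkage, ablation
* `R/decoding.R` — nearest-centroid and SVM decoders, selectivity,
  persistent cells
* `R/fit.R`, `R/session.R` — the `nas_fit` estimator object and session
  I/O (TSV interchange format)

The methods vignette (`vignettes/nas-methods.Rmd`) documents the model,
every tunable parameter with its default and rationale, the synthetic
generator's assumptions, and the statistical reading of the validation
experiments.
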