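---
title: "Quantifying spindle and microtubule dynamics with spindledyn: models and methods"
author: "spindledyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spindle and microtubule dynamics with spindledyn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindledyn)
```

# Scope

`spindledyn` quantifies mitotic spindle assembly in syncytial *Drosophila*
embryos from fluorescence time-lapse movies, together with two companion
assays: AP-MS (affinity purification-mass spectrometry) interactor
filtering against a negative-control database, and fluorescence-based
tubulin polymerisation kinetics. Because raw movies and MS runs for this
class of experiment are rarely deposited, every analysis stage is paired
with a synthetic-data generator that exports its ground truth, so the whole
pipeline is testable end to end at known truth. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
simulation-based validation does and does not demonstrate.

# The imaging model

## Scene

A movie (`simulate_embryo_movie()`) contains one spindle: two centrosomes
(poles) on a horizontal axis moving apart linearly (defaults 10 to 15 µm
over the movie, i.e. 0.025 µm/s of anaphase-B-like elongation), a nuclear
disk (radius 4 µm) centered between them, and EB1-like plus-end comets.
Movies are 41 frames at 5 s (200 s), 96 x 96 px at 0.2 µm/px, rendered
directly as 2-d projections; all downstream analysis is 2-d, so no z-stack
is simulated.

Comets are born at each pole as a Poisson process (8 comets/s per spindle,
split between the poles), with exponential growth-episode lifetimes (mean
40 s) and straight paths at `comet_speed` (default 0.3 µm/s). The process
is burned in for three mean lifetimes before frame 1 so the aster starts at
steady state. Three geometric choices matter downstream and are worth
stating explicitly:

* **Birth offset (1.2 µm).** Comets initiate at the pericentriolar
  periphery, not the centrosome centre. Besides being physically
  reasonable, this keeps the pole spot photometrically clean: without it,
  the comet stream through the localisation window biases the pole
  centroid by 1-3 px and the spindle-elongation rate by 20-30%.
* **Direction switch at NEB.** Before nuclear envelope breakdown comets
  point away from the nucleus (radial asters); from NEB on they are
  directed at the opposite pole with +/- 6 degrees of jitter. The switch is
  what creates the measurable growth front entering the nuclear space.
* **Equator capture (0.5 µm overlap).** Post-NEB comets terminate shortly
  past the spindle equator, as at an antiparallel-overlap midzone. This
  confines each pole's growth signal to its own half-spindle; otherwise
  opposing comets cross the midline and the two growth fronts cannot be
  separated.

At NEB the nucleoplasm gains a diffuse intensity step (25 counts, ramped
over 2 frames), nucleation transiently rises 1.5-fold for 25 s (the comet
burst into the nuclear space), and a diffuse spindle band (transverse
sigma 1 µm) ramps up with a 60-s time constant as the mature spindle forms.
Rendering uses isotropic Gaussians (poles: amplitude 2400, sigma 0.35 µm;
comets: amplitude 150-200, sigma 0.25 µm) over a background of 100 counts.
The camera model applies Poisson shot noise to the signal, then additive
Gaussian read noise (sd 2), then clips to the 16-bit range. Random draws
are split into named streams (comet events per pole, kinematics, noise)
derived from the master seed, so changing the noise level does not perturb
the comet history.

The brightness ratios are not cosmetic. Pole localisation needs the pole
to dominate its 9 x 9 px neighbourhood; Otsu thresholding of the kymograph
needs the *comet cloud*, not the pole, to carry the bright histogram mass
(a histogram dominated by a very bright, small pole class pins the Otsu
threshold above the cloud and erases the growth front). Amplitudes were
chosen once, during simulator design, to make both hold across the
0.2-0.5 µm/s speed range.

The `mora_inhibited` condition differs from `control` only through
`inhibition_factors`: nucleation and speed multipliers (default 0.2 each)
and an additive uniform nucleoplasmic influx at NEB (default 40 counts) --
EB1 entering the nuclear space without forming comets. The magnitude of
the anti-Mora effect is not quantified in the literature this package
models; 0.2 is the package's planted effect size, not a measured value.

## Pole detection and tracking

`detect_poles()` band-passes each frame with a difference of Gaussians
(sigma 2 and 6 px, matched to the pole spot), takes local maxima above
mean + 4 sd of the filtered frame, suppresses non-maxima within 4 px, and
refines each candidate with an intensity-weighted centroid of the
*above-half-maximum* part of the band-passed peak in a 9 x 9 window,
recentered once. The half-max cut is what rejects comet-stream flux
adjacent to the pole; on noiseless Gaussian spots the centroid is exact to
well under 0.1 px.

`track_poles()` links the two brightest persistent candidates by
minimal-summed-displacement assignment, rejecting candidates that jump
more than `max_move` (3 px) per linked frame -- poles move slowly, so
larger jumps are transient comet clusters. Gaps of up to `max_gap` (2)
frames are linearly interpolated and flagged with confidence 0; longer
gaps abort, because at a 5-s cadence longer extrapolation is unreliable. A
3-point running median suppresses single-frame localisation glitches
without biasing linear motion (the median of a linear triplet is its
midpoint). Pole labels A/B are arbitrary but never swap within a track;
comparisons against ground truth minimise over the two pairings. On
default simulations the pooled position error is about 0.07 px RMS and the
elongation rate is recovered to well under 1%.

## Kymographs and the Otsu growth profile

`extract_spindle_profile()` samples each frame by bilinear interpolation at
112 evenly spaced points along the pole-to-pole segment, averaging 5
perpendicular 1-px offsets. Columns are then placed on a finer time raster
(201 bins, about 1 s) by linear interpolation between frames. The raster
exists for one reason: the reference smoothing is a Gaussian of sigma 3.0
*bins*, and at native 5-s columns that means 15 s of temporal smoothing,
which buries the growth front; at 1-s bins it means about 3 s. Composite
kymographs (`composite_kymograph()`) are the element-wise mean over 6-10
spindles (a warning is emitted outside that range) on a nominal
14 µm x 200 s display grid.

`otsu_threshold()` maximises the between-class variance
`w0 * w1 * (mu0 - mu1)^2` over the interior edges of a 256-bin histogram
spanning the data range, averaging tied maximisers. It is tested for
bit-exact agreement with an exhaustive brute-force search, and the whole
contour construction is invariant under affine intensity rescaling (the
threshold rescales; the geometry does not).

`growth_profile_contour()` filters the kymograph (sigma 3 bins,
edge-replicating borders), thresholds it, and extracts the marching-squares
iso-contour. The front position at each time is the farthest
supra-threshold bin from the pole (the pole nearer the supra-threshold
mass), restricted to that pole's half-spindle and requiring the inward
neighbour to be supra-threshold as well. `front_speed` is the
least-squares slope of the front over its rising phase, with two
numerical guards that matter:

* the slope is evaluated at **native frame times only** -- between frames
  the fine-raster columns are intensity cross-fades, and apparent front
  motion inside a cross-fade is an interpolation artefact;
* the fit prefers points **strictly inside** the central 15-85% band of
  the front's advance. The first jump out of the pre-NEB plateau carries
  one-time offsets (the comet birth offset, the blur lead of a smoothed
  edge) that are not front motion, and columns where the front is pinned
  near its ceiling are saturation, not data.

`flatness = 1 / (1 + |front_speed| * T / space_extent)` maps a static
profile to 1 and a fast-advancing one towards 0; it is the scalar used for
the control-versus-inhibited contrast ("the threshold gradient was
essentially flat" becomes flatness near 0.5 versus about 0.17 for
controls).

**Known limitation.** At the 5-s cadence a 0.5 µm/s front crosses the
half-spindle in about two frames, so individual estimates at the top of
the speed range carry 30-60% error; recovery to 15% holds at the median
across the 0.2-0.5 µm/s range, and that is the claim the validation makes.
Speeds well above 0.5 µm/s would need faster acquisition, not a better
estimator.

## NEB-aligned ROI dynamics

`detect_neb()` calls NEB at the first frame whose nuclear mean exceeds the
expanding pre-frame baseline by 3 baseline standard deviations, requiring
the exceedance to persist into the next frame (influx is sustained;
single-frame noise blips are not) and at least 5 baseline frames. Detection
is monotone in influx amplitude and lands within one frame of truth in
over 95% of simulations.

`nuclear_spindle_dynamics()` measures, over 20 frames from 15 s before to
80 s after NEB, the mean and per-pixel SD in a nuclear circle (0.9 x the
nuclear radius -- "just smaller than the nucleus" made explicit) and in a
spindle-region rectangle bounding the pole-pole axis. Both the mean ratio
and the SD ratio are reported because the source descriptions of this
metric differ between a plain nuclear mean and a nuclear/spindle ratio;
the SD ratio with a zero-variance denominator is guarded to 1 and flagged
rather than infinite. In control simulations the SD ratio rises from about
0.04 to about 1.0 within two frames of NEB (comets puncturing the nuclear
space) and declines as the burst subsides and diffuse spindle fluorescence
fills the circle; in inhibited simulations the uniform influx raises the
mean but not the SD, so the ratio stays low. The 3-fold peak-over-baseline
check in the tests is a pipeline choice, not a literature value.

`bleach_correct()` fits `I(t) = A exp(-t/tau) + C` to a per-frame series,
initialised by log-linear regression and polished with Levenberg-Marquardt
(`minpack.lm::nls.lm`; the `nlsLM` wrapper occasionally reports a spurious
singular gradient on exact exponential inputs), then divides by the decay
normalised to t = 0. Known decays with tau between 50 and 200 s are
inverted to well within 1%.

`alignment_time()` implements the NEB-to-congression timing rule: the
first local maximum of the condensed-chromosome mask's principal-axis
aspect ratio after NEB. The simulator plants an area-preserving ellipse
whose ratio ramps to a known peak frame; the measured timing reproduces it
exactly at the default geometry.

# AP-MS filtering

`filter_records()` applies four keep rules per protein: at least 3 unique
peptides, at least 20% sequence coverage, an MS score of at least 50, and
the negative-control rule -- keep if the protein is absent from the
false-positive database or if its bait-run score is at least 1.5-fold its
control score. Thresholds are inclusive on the keep side because the
reference procedure *removes* records strictly below them. The control
database summarises eight control pulldowns by the per-protein maximum
score (the strictest choice; configurable). `abundance_restrict()` then
keeps proteins at 1:100 or more of the bait's score (inclusive; MS score
as the abundance proxy), and `reproducibility_overlap()` reports the
two-run intersection and Jaccard index. The filter is validated by exact
agreement with a naive per-record re-evaluation on 50 simulated 200-record
tables, plus permutation invariance and threshold monotonicity.

The simulator plants true interactors (shared between two runs, passing
every rule, a third of them present weakly in the controls to exercise the
fold rule), contaminants (passing the evidence rules but violating the
fold rule in both runs), and low-evidence decoys (failing at least one
evidence rule), so the planted truth is recoverable exactly by
construction -- which is what makes exact-recovery tests meaningful.

# Polymerisation kinetics

`fit_sigmoid()` fits the four-parameter logistic
`f(t) = f_min + (f_max - f_min) / (1 + exp(-slope (t - t50)))` by
Levenberg-Marquardt, initialised from the data (half-range crossing for
t50, central difference for the slope). Fits are equivariant under
intensity scaling and time shifts; a noiseless logistic is recovered to
1e-6 relative error, and with noise sd 2 on a 100-unit amplitude the
median t50 error is under a minute.

`classify_polymerisation()` calls a curve polymerising when the fit
converged and its *realised* amplitude -- the fitted curve's span between
the first and last assay time -- reaches 5x the residual RMS. The realised
span equals `f_max - f_min` for a genuine sigmoid, but flat noisy controls
occasionally admit degenerate near-linear fits (slope near zero, or t50
far outside the 60-min window) whose nominal amplitude is pure
extrapolation; the span criterion rejects these without any extra tuning.
MT counts per field of view are compared with the same one-tailed pooled
t-test used for spindle lengths (counting is manual in the reference
assay, so counts enter as vectors).

# Statistics

`one_tailed_unpaired_t()` is the classical pooled-variance two-sample
t-test with a one-sided alternative (`stats::t.test` underneath), with
zero-variance degeneracies flagged instead of failing: identical samples
give p = 0.5. Pooled rather than Welch is the default because "unpaired
t-test" without qualification is the classical test; Welch is one argument
away. The directions are explicit arguments -- shorter spindles and more
MTs are biological expectations, not statistical defaults.
`box_summary()` uses type-7 (linear-interpolation) quantiles with
whiskers at the full range, matching the reference plotting convention.
Validation compares p-values against numerical integration of the t
density (1e-8) and a 100,000-permutation oracle (3 Monte-Carlo sd).

# Pipelines and reproducibility

`run_imaging_pipeline()`, `run_tables_pipeline()` and
`run_curves_pipeline()` compose the stages per condition and
`run_full_pipeline()` adds a manifest: package version, config hash, and
an MD5 checksum of each stage's result object. Identical (config, seed)
pairs reproduce identical checksums; all randomness flows from the master
seed through named streams. The default imaging run uses 6 spindles per
condition (each movie is one spindle and nucleus) -- the composite
convention -- and reports the condition contrast: front speeds, flatness,
mean post-NEB SD-ratio peaks, and the one-tailed spindle-length test.
Note that the generator plants no spindle-length difference between
conditions (no effect magnitude is available to plant), so the length
test in a default two-condition run exercises machinery on a true null;
planted-shift power is validated separately.

# What the validation shows, and what it does not

Passing tests demonstrate that each stage recovers known ground truth
under this generator's assumptions: Gaussian optics, Poisson-plus-Gaussian
noise, straight comet paths, a step-plus-ramp NEB, linear pole separation.
Real embryo movies add comet shape anisotropy, bleaching within the
acquisition (here tested only by applying and inverting a known decay),
nuclear import dynamics, neighbouring spindles, and focus drift; none of
these are simulated, so the validation bounds algorithmic error, not
biological generality. Problem sizes in the tests and the acceptance
script (20-50 seeds per property, 40 matched condition pairs, 50 AP-MS
tables) were chosen as the package's standard validation sizes; they keep
Monte-Carlo error comfortably below the tolerances being asserted.
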