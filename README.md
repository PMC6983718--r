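# spindledyn

Quantification of mitotic spindle assembly and microtubule (MT) plus-end
dynamics in syncytial *Drosophila* embryos, with companion analyses for
AP-MS interactor filtering and tubulin polymerisation kinetics.

In early embryos, EB1–GFP marks the growing plus-ends of MTs as moving
"comets": radial asters around the centrosomes before nuclear envelope
breakdown (NEB), then a wave of growth from the spindle poles towards the
equator as the spindle assembles. Acute inhibition of regulators of
centrosomal MT stability suppresses this wave. `spindledyn` turns that
biology into numbers:

* **Spindle pole tracking** — sub-pixel detection of the two centrosomes in
  each frame (band-pass filter, half-max intensity-weighted centroid),
  minimal-displacement linking, and centrosome–centrosome distance series;
  spindle-length sets are compared with box summaries (median, 25–75th
  percentiles, full-range whiskers) and a one-tailed unpaired *t*-test.
* **Kymographs and the Otsu growth profile** — per-spindle and composite
  (6–10 spindle) kymographs along the pole–pole axis (convention
  14 µm × 200 s); after light Gaussian filtering (σ = 3 bins) the Otsu
  threshold — the maximiser of the between-class variance
  w₀w₁(µ₀ − µ₁)² — defines an iso-intensity contour whose front position
  f(t) (farthest supra-threshold bin from the pole) yields a front speed
  (least-squares slope over the rising phase) and a bounded flatness score
  1/(1 + |v|·T/L).
* **NEB-aligned ROI dynamics** — NEB detection from nuclear influx,
  photobleaching correction by exponential-decay fitting, NEB-to-alignment
  timing from the chromosome mask aspect ratio, and the nuclear/spindle
  mean- and SD-ratio series over 20 × 5-s time points from −15 s to +80 s.
* **AP-MS filtering** — the stringent filter (≥3 unique peptides, ≥20%
  coverage, MS score ≥50) plus the negative-control rule (keep if absent
  from an eight-run false-positive database, or ≥1.5-fold enriched over
  it), the 1:100 bait-relative abundance restriction, and two-run
  reproducibility reports.
* **Polymerisation kinetics** — four-parameter logistic fits
  f(t) = f_min + (f_max − f_min)/(1 + e^(−k(t − t₅₀))) to 60-min
  fluorescence curves, polymerising/non-polymerising classification, and
  MT-count comparisons.

Because raw movies and MS runs for this class of experiment are not
publicly deposited, a first-class synthetic-data module
(`simulate_embryo_movie()`, `simulate_apms_tables()`,
`simulate_polymerisation_curve()`) generates inputs with exported ground
truth, and every stage is validated against it. See the methods vignette
(`vignettes/spindledyn-methods.Rmd`) for the models and the numerical
choices.

## Worked example

Simulate a control and an inhibited embryo series, run the full pipeline,
and inspect the condition contrast:

```r
library(spindledyn)

run <- run_full_pipeline(pipeline_config(), seed = 1)
print(run)
#> pipeline_run
#> imaging_bundle: control, mora_inhibited
#>   control: front speed 0.353 um/s, flatness 0.165, median length 15 um
#>   mora_inhibited: front speed 0.0505 um/s, flatness 0.581, median length 15 um
#>   spindle-length t-test p = 0.000364
#>   AP-MS: 16 core interactors, Jaccard 1.000
#>   curves: classification accuracy 100%, MT-count p = 5.23e-10
```

The control composite kymograph shows a growth front advancing at
~0.35 µm/s (the planted comet speed is 0.3 µm/s), giving low flatness;
in the inhibited condition comet nucleation and speed are reduced
five-fold, the Otsu contour is nearly static (front speed ~0.05 µm/s) and
flatness rises towards 1 — the quantitative version of "the threshold
gradient was essentially flat". The AP-MS stage recovers all 15 planted
interactors plus the bait, identically in both simulated runs
(Jaccard 1.0).

Individual stages compose the same way:

```r
sim     <- simulate_embryo_movie(embryo_sim_config(), seed = 3)
track   <- track_poles(sim$movie)
kymo    <- extract_spindle_profile(sim$movie, track)
contour <- growth_profile_contour(kymo)
print(contour)
#> growth-profile contour: threshold 551.3, front speed 0.2934 um/s, flatness 0.176 (pole B)

fit <- fit_sigmoid(simulate_polymerisation_curve(polymer_sim_config(noise_sd = 2), seed = 8))
print(fit)
#> sigmoid_fit: f_min 4.522, f_max 104.2, t50 19.89 min, slope 0.3517 /min
#>   residual RMS 1.793, converged: TRUE, t50 reliable: TRUE
```

The planted curve has f_min = 5, f_max = 105, t₅₀ = 20 min, slope
0.35/min; the fit recovers all four within the noise.

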