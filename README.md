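# condylometry

Digital-phantom morphometry of the mandibular condyle under simulated
fan-beam (FBCT/MDCT) and cone-beam (CBCT) computed tomography.

Binary ("1-bit") bone models segmented from CT are the basis of CAD/CAM
surgical planning around the temporomandibular joint. Cone-beam
acquisitions blur more and separate soft tissue from bone less cleanly than
fan-beam ones, and the models segmented from them under-size thin bone --
most visibly at the floor of the sigmoid notch, a plate only ~2 mm thick.
This package rebuilds the full comparison chain *in silico* so the effect
can be generated, measured and tested against known ground truth:

1. **Phantom** (`phantom_params()`, `build_phantom()`,
   `sample_population()`) -- a parametric constructive-solid condyle +
   ramus with cortical shell and trabecular interior. Parameter defaults
   are the fan-beam population means of the measurement protocol, and all
   11 protocol measurements are known analytically for every parameter set
   (`phantom_truth_numeric()` provides an independent numerical oracle).
2. **Acquisition** (`acquire()`, `default_profiles()`) -- mechanistic image
   formation: contrast compression toward the soft-tissue level, Gaussian
   point-spread blur, box-average voxel integration (the partial volume
   effect) and noise.
3. **Segmentation** (`select_threshold()`, `segment()`,
   `extract_surface()`) -- 256-bin maximum between-class-variance global
   thresholding, largest-component retention, and marching-tetrahedra
   surface extraction to STL/PLY.
4. **Condylometry** (`fit_baseline()`, `detect_landmarks()`, `measure()`,
   `measure_condyle()`) -- the posterior ramus baseline (posterior tangent
   of the sagittal convex hull) and the 11 measurements taken in slabs
   perpendicular to it: basal / middle / top neck lengths, neck height,
   notch-to-neck-top distance, ramus height, basal neck width, head width,
   sigmoid-notch plate thickness, posterior-line angle, and the
   corresponding-angles neck height.
5. **Cohort statistics** (`chi2_independence()`, `compare_groups()`,
   `report()`) -- Pearson chi-square on the cohort table and per-measurement
   FBCT-vs-CBCT comparison routed between one-way ANOVA and Kruskal-Wallis
   by Shapiro-Wilk + Levene diagnostics at alpha = 0.05.
6. **Pipeline** (`experiment_config()`, `run_experiment()`,
   `validate_measurements()`, `paired_modality_bias()`) -- seeded
   end-to-end experiments: phantom population -> two acquisition arms ->
   segmentation -> morphometry -> report.

The methods vignette (`vignettes/condyle-phantom-morphometry.Rmd`)
documents the geometry, the image-formation model, the operator-surrogate
("half-contrast") segmentation threshold the pipeline uses by default, and
every interpretation decision in the measurement protocol.

## Worked example

Build the mean-profile phantom, image it with the shipped cone-beam
profile, segment at the operator-surrogate threshold (half the
soft-to-cortical contrast of that modality) and measure:

```r
library(condylometry)
p     <- phantom_params()                      # FBCT population means
ph    <- build_phantom(p, spacing = 0.25)      # volume + ground truth
img   <- acquire(ph$volume, default_profiles()$cbct, seed = 7)
thr   <- p$density_soft + 0.5 * 0.7 * (p$density_cortical - p$density_soft)
model <- segment(img, threshold = thr)
mesh  <- extract_surface(model)
measure_condyle(mesh)
```

```
<measurement_set> (mm; angle in degrees)
  length_neck_basal                  21.044
  length_neck_top                    11.844
  distance_sigmoidnotch_necktop      15.374
  height_neck                        10.457
  length_neck_middle                 12.991
  ramus_height                       69.500
  width_neck_basal                   10.316
  width_head                         20.806
  thickness_sigmoid_notch             1.995
  angle_posteriorline_notchpoint     13.369
  height_neck_new_classification     16.961
```

The phantom's true notch-plate thickness is 2.15 mm; the cone-beam chain
reads 2.00 mm -- the thin-bone partial-volume undersizing the package
exists to study. Under the fan-beam profile (or an identity acquisition)
the same phantom reads within ~0.1 mm of truth on that measurement, and a
paired experiment (`paired_modality_bias()`) gives a positive pooled
FBCT - CBCT difference for the notch plate.

A full two-arm study with statistics:

```r
cfg <- experiment_config(n_per_arm = 30, seed = 1)
rep <- run_experiment(cfg)     # ~minutes; per-condyle table + comparisons
print(rep)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/condylometry.R` (`acquire`, `segment`, `measure`, `run-study`,
`validate` subcommands).

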