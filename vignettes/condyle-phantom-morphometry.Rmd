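---
title: "Phantom-based condylar morphometry and the fan-beam / cone-beam comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based condylar morphometry and the fan-beam / cone-beam comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Surgical planning around the temporomandibular joint increasingly relies on
1-bit (binary) bone models segmented from computed tomography. Fan-beam
(FBCT/MDCT) and cone-beam (CBCT) acquisitions of the same anatomy do not
yield identical models: cone-beam reconstructions blur more, separate soft
tissue from bone less cleanly, and consequently under-size thin bone such as
the floor of the sigmoid notch, where the mandibular plate is only about
2 mm thick. Clinical studies quantify this by applying a standardized
11-measurement condylar morphometry protocol to segmented models from both
modalities and comparing the distributions per measurement.

This package rebuilds that entire chain at desk scale, replacing patients
with a parametric digital phantom whose geometry -- and therefore every one
of the 11 measurements -- is known exactly. That makes three questions
testable that patient data cannot answer directly: does the measurement
protocol recover truth (parameter recovery); does the simulated image
formation reproduce the thin-bone undersizing with the right sign and size
(modality bias); and is the statistical layer calibrated (type-I error at
the nominal level).

# The condyle phantom

The phantom is a constructive solid in a fixed "baseline frame": x
mediolateral, y anteroposterior (anterior positive, measured from the
posterior baseline plane), z craniocaudal along the baseline. Four
primitives are united:

* a **ramus body** slab with a shallow coned lower end (unique lowest
  point),
* a **condylar neck** column whose posterior border is inset from the
  baseline at the notch level and returns towards it below the head (a
  posterior concavity), and whose anterior border bulges parabolically with
  its maximum at the neck-middle level,
* a thin **coronoid plate** of mediolateral thickness `notch_thickness`
  carrying the sigmoid notch: its top edge is a parabola with apex at the
  notch floor, capped by the anterior ridge `notch_depth` above it,
* a **condylar head** modelled as a p = 4 superellipsoid, tangent to the
  baseline plane posteriorly, with its top at the total ramus height. The
  quartic profile keeps the head's sides steep near the head-reference
  level, which matters because two of the protocol's constructions amplify
  small errors in the anterior head boundary (see below); a condylar head
  is in any case much wider than it is tall.

Each of the named parameters maps one-to-one onto a measurement of the
protocol (basal/middle/top neck lengths, neck height, ramus height, head
and neck widths, notch plate thickness), and the defaults are the published
fan-beam population means of those measurements, so `phantom_params()`
describes the average condyle of that population. The remaining
measurements -- the notch-to-neck-top distance, the posterior-line angle
and the corresponding-angles neck height -- are emergent; the structural
shape constants (posterior inset 1.9 mm, head posterior clearance 0.28 mm
at the default profile, both scaled with their governing length parameter)
were derived once from the requirement that all eleven published means be
realized simultaneously by a single solid. That requirement has a
non-obvious consequence worth recording: the published means are mutually
consistent only if the neck's posterior border is inset at least 1.6 mm
anterior of the baseline at the basal level while the head returns to
almost touch the line -- i.e. the population's average posterior border is
concave, which the phantom therefore builds in.

Tissue is three-valued: cortical shell (default 2 mm, eroded
morphologically from the bone solid), trabecular interior, soft background
(defaults 1400 / 800 / 50 arbitrary density units), so the unblurred volume
histogram has exactly three modes.

Population variation multiplies each length-type parameter by an
independent truncated normal with coefficient of variation `cv` (default
0.1). The published per-measurement standard deviations mix anatomical and
modality variance and therefore cannot be plugged in directly; 10% is a
typical anatomical CV for craniofacial lengths. Draws violating the
parameter orderings or the geometric feasibility of the solid are redrawn.

Ground truth ships in closed form from the constructive geometry;
`phantom_truth_numeric()` re-derives all eleven values by dense
extreme-point search on the implicit surface (0.02 mm sagittal sampling,
with parabola-apex refinement of the notch floor), and the test suite
asserts agreement to 0.05 mm. Truth is never computed from the
voxelisation.

## What the generator does not emulate

No teeth, no trabecular texture, no metal or motion artifacts, no
field-of-view truncation, no left-right asymmetry (the mirrored pair of a
subject is an exact reflection), and the phantom is always "healthy".
Passing tests therefore demonstrate correctness of the measurement chain
and of the mechanistic partial-volume story, not performance on clinical
images.

# Image formation

`acquire()` implements the minimal mechanistic model of the modality
difference: (1) linear contrast compression of densities towards the
soft-tissue level (the histogram mode) by `contrast_scale`; (2) isotropic
Gaussian point-spread blur `psf_sigma`; (3) box-average resampling to the
`voxel_out` grid -- the voxel-integration step that produces the partial
volume effect; (4) additive white Gaussian noise. The shipped profiles are
FBCT: 0.5 mm voxels, 0.3 mm PSF, full contrast, noise 10; CBCT: 0.5 mm
voxels, 1.0 mm PSF, contrast 0.7, noise 15. Equal voxel sizes are
deliberate: they isolate PSF and contrast as the drivers of the modality
difference. The numbers themselves are placeholders calibrated only by two
contracts: the cone-beam profile blurs more and separates contrast less,
and the blur must be strong enough that a ~2 mm plate falls in the
thin-structure regime (thickness below roughly four PSF sigma) where the
closed-form erf analysis predicts measurable undersizing. No beam
hardening, scatter field, cone-angle dependence, or projection-domain
physics is modelled.

# Segmentation and the operator surrogate

`select_threshold()` is the reproducible stand-in for "individual histogram
analysis": the 256-bin maximum between-class-variance (Otsu) threshold,
ties toward the lower boundary. `segment()` thresholds, keeps the largest
26-connected component (the automated counterpart of manually delineating
the mandible) and records the threshold used.

One finding of this implementation deserves emphasis because it shapes the
pipeline default. Any purely histogram-derived, affine-equivariant selector
-- Otsu included -- places the global threshold near the midpoint of the
soft and *mean-bone* levels, i.e. *below* half of the soft-to-cortical
rise. Below that half-rise, a blurred bone surface crosses the threshold
*outside* its true position, so a blurrier modality segments *larger*, the
opposite of what is observed clinically. The clinical workflow resolves
this with a human: suggested thresholds are visually adjusted until the
model overlaps the bone edge, which anchors the threshold at the half-rise
of the soft-to-cortical contrast -- an anatomical anchor no histogram
functional can supply once blur has destroyed the cortical peak. The
pipeline therefore models the confirmation step explicitly: its default
segmentation threshold is `"half-contrast"`, the value halfway between the
soft level and the modality's contrast-scaled cortical level, computed from
the known tissue densities of the phantom (the simulation's stand-in for
the operator's anatomical knowledge). With that anchor, first-order edge
offsets vanish in both arms and the residual effects are pure partial
volume: thin plates lose peak amplitude and read thinner under the wider
PSF, and convex surfaces shrink by roughly sigma squared times curvature.
Both push the cone-beam arm towards smaller values, the thin sigmoid-notch
plate hardest. Raw Otsu remains available (`threshold = "auto"`) and its
oracle equivalence, shift equivariance and monotonicity are tested, but
under raw Otsu the modality ordering reverses -- a mechanistic statement
about histogram thresholds on blurred images, reproduced honestly by this
package rather than hidden.

`extract_surface()` runs marching tetrahedra (Kuhn subdivision, level 0.5)
on the model's occupancy field. Iso-surfacing the raw 0/1 field
overestimates oblique surface area by up to ~9% (orientation aliasing), so
the field is first smoothed with a 0.7-voxel Gaussian, with `0.55 * mask`
blended back as a floor so no foreground voxel can vanish; on a 10 mm
sphere this brings the area error to ~2% while conserving volume to a
fraction of a percent. Two side effects are documented rather than papered
over: an isolated voxel extracts as a small octahedron of well under one
voxel volume (any midpoint-interpolating extraction behaves this way), and
the mesh volume can exceed the voxel-count volume by up to ~0.1% on convex
shapes.

# The measurement protocol

`fit_baseline()` constructs the posterior ramus line as the most nearly
craniocaudal edge of the sagittal-projection convex hull that supports the
whole projection on its anterior side; supporting points are logged. All
eleven measurements are taken in the baseline frame (u along the line, v
anteroposterior, w mediolateral); a "level" is a slab one output voxel
thick perpendicular to u, and extents are vertex-based. The sigmoid notch
is detected on the upper envelope of the sagittal profile as the deepest
interior local minimum with sufficient prominence, then refined by fitting
a parabola to the local top edge (the notch floor is a parabola by
construction, and real notch floors are smooth); the condylion and lowest
ramus point are centroids of the extreme vertex clusters along u, which is
robust when the extreme surface is locally flat.

Three constructions needed interpretation:

* **Notch plate thickness** ("width 1 mm below the sigmoid notch"): the
  slab one millimetre below the notch level also contains the condylar
  neck, whose width is five times the plate's, so a literal whole-slab
  extent cannot yield the published ~2 mm. The measurement is therefore
  local: within an anteroposterior window of +/- 1 mm around the notch, the
  *minimum* mediolateral extent over overlapping sub-slabs. The minimum
  (rather than a single central slab) makes the value immune to the
  partial-volume webbing that heavy blur creates in the concave corner
  between plate and neck.
* **Corresponding-angles neck height**: the published construction pairs
  the posterior-line/notch angle with an equal angle at the most anterior
  point of the head-reference level. Read literally as "distance along the
  baseline between the two levels" it degenerates to the ordinary neck
  height, which contradicts the two distinct published values. The
  non-degenerate corresponding-angles reading implemented here is the
  distance, parallel to the baseline, from the top anterior point to the
  medial arm (the ray from the lowest baseline point through the notch).
  At the default parameters this reproduces the published population mean
  of that measurement exactly; the output flags the value as
  interpretation-dependent.
* **Head reference level**: placed `head_fraction` (default 0.15) of the
  condylion-to-notch height below the condylion, recorded in the output.

Because the medial-arm construction divides by the notch's anteroposterior
offset, it amplifies small boundary errors about four-fold; the anterior
extreme points of the basal and top levels are therefore interpolated to
the exact level with a short linear fit instead of taking a raw vertex,
which removes the half-slab bias that discretisation would otherwise
inject.

# Statistics

`chi2_independence()` is the Pearson chi-square without continuity
correction (the expected counts in this design are large).
`compare_groups()` routes between one-way ANOVA and Kruskal-Wallis: ANOVA
only if both groups pass Shapiro-Wilk at 0.05 and Levene's test (classic,
mean-centred; configurable to Brown-Forsythe) passes at 0.05. Significance
is per-measurement at 0.05 with no multiplicity correction, replicating the
protocol being modelled; both choices are limitations, and the two condyles
of a subject are treated as independent observations, as in the source
protocol. On synthetic data the route a measurement takes need not match
the one reported for patient data, and nothing attempts to force it.

# Numerical choices and problem sizes

Default build spacing is 0.25 mm (the thinnest structure must span at
least two build voxels; builds finer than either simulated modality).
Voxelisation quantises each boundary to about half a build voxel, and the
amplified constructions inherit roughly four times that, so recovery is
resolution-limited, not algorithm-limited: the test suite checks median
absolute recovery error under 0.3 mm over 30 sampled phantoms at 0.25 mm,
and the mean-profile phantom measured at 0.2 mm sits within 0.2 mm on
every measurement. The paired modality comparison uses 20 matched phantom
pairs; the null calibration uses 2000 Monte-Carlo replicates at group size
50. Per-stage random streams are derived from the master seed by a fixed
affine scheme modulo 2^31 - 1, so every experiment is exactly reproducible
from one integer.

# Known limitations

The phantom is one idealised shape family; the acquisition model has no
scatter, beam hardening or spatially varying PSF; the operator surrogate
uses the generative tissue densities that a real operator would only know
approximately; the corresponding-angles measurement is one defensible
reading of an ambiguous construction; and the statistics layer inherits
the per-measurement testing scheme of the protocol it models, including
its lack of multiplicity control.
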