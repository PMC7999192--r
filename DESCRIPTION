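Package: condylometry
Title: Digital-Phantom Morphometry of the Mandibular Condyle in Simulated
    Fan- and Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric digital phantoms of the mandibular ramus, condylar
    neck and condylar head with analytically known geometry; a mechanistic
    simulator of fan-beam and cone-beam CT image formation (contrast scaling,
    Gaussian point-spread blur, voxel box-integration and noise, i.e. the
    partial volume effect); histogram-based global-threshold bone
    segmentation into 1-bit models and triangulated surfaces; the
    11-measurement condylar morphometry protocol built on the posterior ramus
    baseline; and the cohort statistics layer (chi-square independence,
    normality-routed ANOVA versus Kruskal-Wallis group comparison) used to
    study modality-dependent undersizing of thin bone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
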