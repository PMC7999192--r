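#' Parametric condyle-ramus phantom parameters
#'
#' Creates the parameter set of the digital condyle phantom.  The defaults are
#' the fan-beam (FBCT) population means of the condylar morphometry protocol,
#' so `phantom_params()` with no arguments describes the "average" condyle:
#' ramus height 69.61 mm, basal neck length 21.27 mm, head width 20.74 mm,
#' sigmoid-notch plate thickness 2.15 mm, and so on.
#'
#' All lengths are in mm, the notch angle in degrees, densities in arbitrary
#' CT-like units.  Invariants enforced: every length strictly positive;
#' `notch_thickness < neck_basal_width < head_width` (the notch plate is the
#' thin-bone region); `neck_top_length < neck_middle_length <
#' neck_basal_length` (the neck tapers towards the head); `density_soft <
#' density_trabecular < density_cortical`.
#'
#' @param ramus_height total craniocaudal extent of the model (mm).
#' @param neck_basal_length anteroposterior extent at the sigmoid-notch level
#'   (mm).
#' @param neck_top_length anteroposterior extent at the condylar-head
#'   reference level (mm).
#' @param neck_middle_length anteroposterior extent midway between the basal
#'   and top levels (mm).
#' @param neck_height distance along the baseline between the basal and top
#'   levels (mm).
#' @param head_width mediolateral width of the condylar head (mm).
#' @param neck_basal_width mediolateral width of the neck at the basal level
#'   (mm).
#' @param notch_thickness mediolateral thickness of the bone plate carrying
#'   the sigmoid notch (mm); the thin-bone structure.
#' @param notch_depth depth of the sigmoid notch below the coronoid ridge
#'   crest (mm).
#' @param notch_angle angle (degrees) between the posterior baseline and the
#'   ray from the lowest baseline point to the notch floor.  The default is
#'   the value at which the corresponding-angles neck-height construction of
#'   the measurement protocol evaluates to its published population mean for
#'   the default lengths.
#' @param cortical_thickness cortical shell thickness (mm).
#' @param density_cortical,density_trabecular,density_soft tissue densities
#'   (arbitrary units), ordered soft < trabecular < cortical.
#' @param seed integer seed recorded with the parameter set.
#' @return An object of class `phantom_params` (a named list).
#' @export
#' @examples
#' p <- phantom_params()
#' p$neck_basal_length
phantom_params <- function(ramus_height = 69.61,
                           neck_basal_length = 21.27,
                           neck_top_length = 12.07,
                           neck_middle_length = 13.18,
                           neck_height = 10.26,
                           head_width = 20.74,
                           neck_basal_width = 10.29,
                           notch_thickness = 2.15,
                           notch_depth = 3.0,
                           notch_angle = 13.05997,
                           cortical_thickness = 2.0,
                           density_cortical = 1400,
                           density_trabecular = 800,
                           density_soft = 50,
                           seed = 1L) {
  p <- structure(list(
    ramus_height = ramus_height,
    neck_basal_length = neck_basal_length,
    neck_top_length = neck_top_length,
    neck_middle_length = neck_middle_length,
    neck_height = neck_height,
    head_width = head_width,
    neck_basal_width = neck_basal_width,
    notch_thickness = notch_thickness,
    notch_depth = notch_depth,
    notch_angle = notch_angle,
    cortical_thickness = cortical_thickness,
    density_cortical = density_cortical,
    density_trabecular = density_trabecular,
    density_soft = density_soft,
    seed = as.integer(seed)), class = "phantom_params")
  validate_phantom_params(p)
  p
}

# names of the parameters sampled by sample_population (the length-type ones)
length_param_names <- function() {
  c("ramus_height", "neck_basal_length", "neck_top_length",
    "neck_middle_length", "neck_height", "head_width", "neck_basal_width",
    "notch_thickness", "notch_depth", "cortical_thickness")
}

#' Validate phantom parameters
#'
#' Checks both the type invariants (positivity, width and taper orderings,
#' density ordering) and the geometric feasibility of the constructive solid
#' (the condylar head solve, the clearance of the coronoid ridge below the
#' neck-middle level, and the integrity of the thin-plate window used by the
#' notch-thickness measurement).
#'
#' @param p a [phantom_params()] object (or bare named list).
#' @param quiet if `TRUE`, return `FALSE` instead of throwing on violation.
#' @return `TRUE` invisibly (or `FALSE` when `quiet = TRUE` and invalid).
#' @export
validate_phantom_params <- function(p, quiet = FALSE) {
  fail <- function(msg) {
    if (quiet) return(FALSE)
    stop_condylometry(paste0("invalid phantom parameters: ", msg),
                      "condylometry_param_error")
  }
  lens <- unlist(p[length_param_names()])
  if (any(!is.finite(lens)) || any(lens <= 0))
    return(fail("all lengths must be strictly positive"))
  if (!(p$notch_thickness < p$neck_basal_width &&
        p$neck_basal_width < p$head_width))
    return(fail("need notch_thickness < neck_basal_width < head_width"))
  if (!(p$neck_top_length < p$neck_middle_length &&
        p$neck_middle_length < p$neck_basal_length))
    return(fail("need neck_top_length < neck_middle_length < neck_basal_length"))
  if (!(p$density_soft < p$density_trabecular &&
        p$density_trabecular < p$density_cortical))
    return(fail("need density_soft < density_trabecular < density_cortical"))
  if (!is.finite(p$notch_angle) || p$notch_angle <= 0 || p$notch_angle >= 60)
    return(fail("notch_angle must be in (0, 60) degrees"))

  g <- try(phantom_geometry(p), silent = TRUE)
  if (inherits(g, "try-error"))
    return(fail(attr(g, "condition")$message))
  s <- g$scale
  # anterior extent of the head at the neck-middle level must stay behind
  # the neck's own anterior border (the neck bulge owns the middle slab)
  sm <- (max(0, 1 - ((g$U_mid - g$U_c) / g$a_U)^4))^(1 / 4)
  head_ant_mid <- g$V_c + g$a_V * sm
  ok <- g$U_b > 0.05 * s &&
    g$head_bottom > g$U_b + 0.25 * s &&
    head_ant_mid < g$A_mid - 0.02 * s &&
    g$U_neck_top < g$U_t - 0.25 * s &&
    g$U_r < g$U_mid - 0.25 * s &&
    g$U_r > g$U_n + 0.1 * s &&
    g$A_n < g$V_notch - 1 - 0.2 &&
    g$V_notch + sqrt(p$notch_depth / g$kappa) < g$V_rf - 0.2 * s &&
    g$V_notch > g$A_mid + 0.1 * s
  if (!ok) return(fail("parameters give an infeasible condyle geometry"))
  invisible(TRUE)
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("<phantom_params>\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-22s %d\n", "seed", x$seed))
  invisible(x)
}

#' Sample a phantom population
#'
#' Draws `n` independent parameter sets around a mean profile.  Each length
#' parameter is drawn from a normal law centred on its profile value with
#' standard deviation `cv` times that value; draws violating the parameter
#' invariants are rejected and redrawn, so the marginals are truncated
#' normals.  The notch angle and the tissue densities are kept at the profile
#' values.  Deterministic given `seed`.
#'
#' @param n number of individuals (>= 1).
#' @param means_profile a [phantom_params()] giving the population means;
#'   defaults to the FBCT mean profile.
#' @param cv coefficient of variation, in (0, 0.5].
#' @param seed integer seed.
#' @return A list of `n` [phantom_params()] objects.
#' @export
#' @examples
#' pop <- sample_population(3, cv = 0.05, seed = 42)
#' sapply(pop, `[[`, "ramus_height")
sample_population <- function(n, means_profile = phantom_params(), cv = 0.1,
                              seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop_condylometry("n must be a positive count")
  if (!is.finite(cv) || cv <= 0 || cv > 0.5)
    stop_condylometry("cv must lie in (0, 0.5]")
  validate_phantom_params(means_profile)
  nms <- length_param_names()
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in 1:200) {
        p <- means_profile
        for (nm in nms)
          p[[nm]] <- rnorm(1, mean = means_profile[[nm]],
                           sd = cv * means_profile[[nm]])
        p$seed <- derive_seed(seed, "individual", i)
        class(p) <- "phantom_params"
        if (isTRUE(validate_phantom_params(p, quiet = TRUE))) return(p)
      }
      stop_condylometry(
        "could not draw feasible phantom parameters after 200 attempts")
    })
  })
}
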