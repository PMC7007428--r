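# Synthetic ATR-FTIR tissue spectra with the cohort structure the analysis
# assumes: Gaussian/Lorentzian absorbance bands, a slowly varying baseline,
# per-patient band-amplitude random effects, per-spectrum multiplicative
# gain scatter, additive detector noise, and class-specific marker effects.

#' Cohort acquisition design
#'
#' @param class_sizes named integer vector of patients per class
#'   (names from `G1`, `G2`, `G1R`), all >= 1.
#' @param replicates_per_patient spectra acquired per tissue sample.
#' @param axis_lo,axis_hi acquisition range in cm^-1.
#' @param resolution spectral resolution in cm^-1.
#' @param spacing point spacing of the stored axis in cm^-1; defaults to
#'   `resolution / 2` (the usual one-level zero-filling of FTIR
#'   interferograms), giving 226 points across 1800-900 cm^-1 at the
#'   default 8 cm^-1 resolution.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(class_sizes = c(G1 = 70, G2 = 24, G1R = 5),
                          replicates_per_patient = 10,
                          axis_lo = 400, axis_hi = 4000,
                          resolution = 8, spacing = resolution / 2) {
  if (!length(class_sizes)) stop("class_sizes must be non-empty", call. = FALSE)
  stopifnot(all(class_sizes >= 1), replicates_per_patient >= 1,
            axis_lo < axis_hi, resolution > 0, spacing > 0)
  if (!all(names(class_sizes) %in% GRADE_CODES))
    stop("class_sizes names must be class codes", call. = FALSE)
  structure(list(class_sizes = class_sizes,
                 replicates_per_patient = replicates_per_patient,
                 axis_lo = axis_lo, axis_hi = axis_hi,
                 resolution = resolution, spacing = spacing),
            class = "cohort_design")
}

#' Wavenumber axis of a cohort design (high-to-low, spectrometer convention)
#' @param design a `cohort_design`.
#' @return numeric vector of wavenumbers in cm^-1.
#' @export
design_axis <- function(design) {
  seq(design$axis_hi, design$axis_lo, by = -design$spacing)
}

#' Absorbance band model
#'
#' @param bands data.frame with columns `center` (cm^-1), `width` (Gaussian
#'   sd / Lorentzian half-width, cm^-1), `amplitude` (absorbance units,
#'   >= 0) and `shape` (`"gaussian"` or `"lorentzian"`).
#' @param baseline_coeffs polynomial coefficients (constant first) of the
#'   deterministic baseline, in a wavenumber axis rescaled to [-1, 1].
#' @param scatter_sd sd of the per-spectrum log-normal multiplicative gain.
#' @param noise_sd sd of additive per-point noise (absorbance units).
#' @param patient_sd sd of the per-patient, per-band log-normal amplitude
#'   random effect; either a scalar or a named per-class vector — the
#'   grade I cohort, spanning several histological subtypes, is modelled as
#'   more heterogeneous than grade II or the small recurrence group.
#' @param center_jitter_sd sd (cm^-1) of the per-patient random shift of
#'   each band centre, emulating inter-patient peak-position variability;
#'   scalar or named per-class vector, like `patient_sd`.
#' @param replicate_amp_sd sd of the per-spectrum, per-band log-normal
#'   amplitude jitter, emulating within-sample heterogeneity across the
#'   replicate sampling locations.
#' @return an object of class `band_model`.
#' @export
band_model <- function(bands, baseline_coeffs = c(0.05, 0.01, 0.005),
                       scatter_sd = 0.05, noise_sd = 0.005,
                       patient_sd = 0.1, center_jitter_sd = 0,
                       replicate_amp_sd = 0) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amplitude", "shape") %in% names(bands)),
            all(bands$width > 0), all(bands$amplitude >= 0),
            all(bands$shape %in% c("gaussian", "lorentzian")),
            noise_sd >= 0, scatter_sd >= 0, all(patient_sd >= 0),
            center_jitter_sd >= 0, replicate_amp_sd >= 0)
  structure(list(bands = bands, baseline_coeffs = baseline_coeffs,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 patient_sd = patient_sd, center_jitter_sd = center_jitter_sd,
                 replicate_amp_sd = replicate_amp_sd),
            class = "band_model")
}

#' Class-specific marker effects
#'
#' Each row describes one marker: at `wavenumber`, spectra of `target_class`
#' have their local band intensity raised (`direction = "up"`) or lowered
#' (`"down"`) by a `magnitude` fraction relative to the base class profile.
#'
#' @param wavenumber numeric, cm^-1.
#' @param direction `"up"` or `"down"`.
#' @param magnitude fractional amplitude change, >= 0.
#' @param target_class class code the effect applies to.
#' @return data.frame of class effects (one row per marker).
#' @export
class_effects <- function(wavenumber, direction, magnitude, target_class) {
  stopifnot(all(direction %in% c("up", "down")), all(magnitude >= 0),
            all(target_class %in% GRADE_CODES))
  data.frame(wavenumber = wavenumber, direction = direction,
             magnitude = magnitude, target_class = target_class,
             stringsAsFactors = FALSE)
}

#' Default study design: cohort, band model and marker effects
#'
#' Emulates the acquisition design of the meningioma study the package
#' models: 70 grade I, 24 grade II and 5 recurrent grade I patients, ten
#' replicate spectra per tissue sample, 4000-400 cm^-1 at 8 cm^-1
#' resolution. Bands sit at the classic biofingerprint assignments (lipid
#' ester C=O 1750, Amide I 1650, Amide II 1550, CH2 bending 1470, Amide III
#' 1260, asymmetric/symmetric phosphate 1225/1080, carbohydrate C-O-C 1155,
#' glycogen 1030, protein phosphorylation 970 cm^-1) plus broad background
#' bands. Grade II and recurrence marker effects are placed at the
#' wavenumbers reported discriminant for those comparisons, with the
#' reported higher/lower intensity directions.
#'
#' @param effect_magnitude fractional intensity change applied at every
#'   marker wavenumber (default 0.15).
#' @return list with elements `design` (`cohort_design`), `bands`
#'   (`band_model`) and `effects` (class-effect data.frame).
#' @export
default_study_design <- function(effect_magnitude = 0.15) {
  design <- cohort_design()
  bands <- band_model(
    bands = data.frame(
      center    = c(1750, 1650, 1550, 1470, 1260, 1225, 1155, 1080, 1030, 970,
                    1400, 1100, 3290, 2925),
      width     = c(14, 18, 16, 14, 16, 14, 12, 16, 12, 12,
                    45, 45, 130, 45),
      amplitude = c(0.25, 1.00, 0.70, 0.35, 0.30, 0.35, 0.25, 0.45, 0.30, 0.20,
                    0.18, 0.20, 0.60, 0.25),
      shape     = "gaussian"
    ),
    baseline_coeffs = c(0.05, 0.01, 0.005),
    scatter_sd = 0.05,
    noise_sd = 0.005,
    patient_sd = c(G1 = 0.15, G2 = 0.08, G1R = 0.05),
    center_jitter_sd = c(G1 = 6, G2 = 2, G1R = 1.5),
    replicate_amp_sd = 0.05
  )
  # Grade II markers (vs grade I): up = higher intensity in grade II.
  g2 <- class_effects(
    wavenumber   = c(1651, 1593, 1546, 1500, 1454, 1377, 1227, 1122),
    direction    = c("down", "down", "up", "up", "down", "down", "down", "up"),
    magnitude    = effect_magnitude,
    target_class = "G2"
  )
  # Recurrence markers (vs grade I): up = higher intensity in recurrence.
  g1r <- class_effects(
    wavenumber   = c(1755, 1693, 1477, 1423, 1400, 1369, 1346, 1246),
    direction    = c("down", "up", "down", "up", "down", "down", "down", "up"),
    magnitude    = effect_magnitude,
    target_class = "G1R"
  )
  list(design = design, bands = bands, effects = rbind(g2, g1r))
}

band_profile <- function(x, center, width, shape) {
  if (shape == "gaussian") exp(-(x - center)^2 / (2 * width^2))
  else 1 / (1 + ((x - center) / width)^2)
}

# width of the local multiplicative bump an effect imprints; capped so that
# markers attached to broad background bands stay spectroscopically narrow
effect_bump_sd <- function(band_width) min(band_width, 12)

# attach an effect to a band: nearest center whose 3-sigma support contains
# the effect wavenumber; otherwise warn and attach to the nearest band.
attach_band <- function(wavenumber, bands) {
  d <- abs(bands$center - wavenumber)
  inside <- d <= 3 * bands$width
  if (any(inside)) {
    idx <- which(inside)
    idx[which.min(d[inside])]
  } else {
    warning(sprintf(
      "effect at %g cm^-1 lies outside all band supports; attaching to nearest band at %g cm^-1",
      wavenumber, bands$center[which.min(d)]), call. = FALSE)
    which.min(d)
  }
}

#' Imprint one class effect on a spectrum
#'
#' The effect multiplies the spectrum by a local Gaussian-windowed gain
#' centred at the effect wavenumber: `up` scales the marker position by
#' `(1 + magnitude)`, `down` divides by it, and the perturbation decays with
#' the attached band's (capped) width, leaving the spectrum essentially
#' unchanged outside the band support. `up` followed by `down` of equal
#' magnitude at the same wavenumber is an exact identity.
#'
#' @param spectrum numeric intensity vector on `wavenumbers`.
#' @param effect a single-row class-effect data.frame (see [class_effects()]).
#' @param bands a `band_model`.
#' @param wavenumbers the axis of `spectrum`.
#' @return the perturbed spectrum.
#' @export
inject_effect <- function(spectrum, effect, bands, wavenumbers) {
  stopifnot(nrow(effect) == 1)
  g <- effect_gain(wavenumbers, effect, bands)
  spectrum * g
}

# multiplicative gain field of a set of effects on a given axis
effect_gain <- function(wavenumbers, effects, bands) {
  g <- rep(1, length(wavenumbers))
  if (is.null(effects) || !nrow(effects)) return(g)
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    if (e$magnitude == 0) next
    b <- attach_band(e$wavenumber, bands$bands)
    s <- effect_bump_sd(bands$bands$width[b])
    w <- exp(-(wavenumbers - e$wavenumber)^2 / (2 * s^2))
    sgn <- if (e$direction == "up") 1 else -1
    g <- g * (1 + e$magnitude)^(sgn * w)
  }
  g
}

class_param <- function(value, class) {
  if (!is.null(names(value)) && class %in% names(value))
    unname(value[class])
  else unname(value[1])
}

#' Generate a synthetic cohort of ATR-FTIR spectra
#'
#' One spectrum per (patient, replicate). A patient's noiseless signal is
#' the band sum with per-patient log-normal band-amplitude factors and the
#' patient's class-effect gain field; each replicate multiplies it by a
#' log-normal per-spectrum gain, adds the polynomial baseline and additive
#' Gaussian noise. Bit-identical output for a fixed seed.
#'
#' @param design a `cohort_design`.
#' @param bands a `band_model`.
#' @param effects class-effect data.frame (may be `NULL` or empty).
#' @param seed integer RNG seed (mandatory: generation is always seeded).
#' @return a `spectral_dataset` with `stage_tag = "raw"`.
#' @export
generate_cohort <- function(design, bands, effects = NULL, seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(bands, "band_model"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!length(design$class_sizes)) stop("empty class_sizes", call. = FALSE)
  set.seed(seed)
  x <- design_axis(design)
  p <- length(x)
  nb <- nrow(bands$bands)
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)      # axis rescaled [-1,1]
  baseline <- rowSums(vapply(seq_along(bands$baseline_coeffs), function(k) {
    bands$baseline_coeffs[k] * u^(k - 1)
  }, numeric(p)))

  classes <- names(design$class_sizes)
  reps <- design$replicates_per_patient
  rows <- list(); ids <- list(); pats <- list(); labs <- list()
  for (cl in classes) {
    gain_field <- effect_gain(x, effects[effects$target_class == cl, , drop = FALSE],
                              bands)
    psd <- class_param(bands$patient_sd, cl)
    cjsd <- class_param(bands$center_jitter_sd, cl)
    for (i in seq_len(design$class_sizes[[cl]])) {
      pid <- sprintf("%s_P%02d", cl, i)
      band_fac <- exp(stats::rnorm(nb, 0, psd))
      centers <- bands$bands$center + stats::rnorm(nb, 0, cjsd)
      profiles <- vapply(seq_len(nb), function(b) {
        bands$bands$amplitude[b] * band_fac[b] *
          band_profile(x, centers[b], bands$bands$width[b],
                       bands$bands$shape[b])
      }, numeric(p))                                    # p x nb
      rep_fac <- matrix(exp(stats::rnorm(reps * nb, 0,
                                         bands$replicate_amp_sd)),
                        nrow = nb)                      # nb x reps
      signal <- t(profiles %*% rep_fac) *
        matrix(gain_field, reps, p, byrow = TRUE)       # reps x p
      gains <- exp(stats::rnorm(reps, 0, bands$scatter_sd))
      noise <- matrix(stats::rnorm(reps * p, 0, bands$noise_sd), nrow = reps)
      spec <- signal * gains + matrix(baseline, reps, p, byrow = TRUE) + noise
      rows[[length(rows) + 1]] <- spec
      ids[[length(ids) + 1]] <- sprintf("%s_S%02d", pid, seq_len(reps))
      pats[[length(pats) + 1]] <- rep(pid, reps)
      labs[[length(labs) + 1]] <- rep(cl, reps)
    }
  }
  spectral_dataset(x, do.call(rbind, rows), unlist(ids), unlist(pats),
                   unlist(labs), stage_tag = "raw")
}
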