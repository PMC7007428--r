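# Spectral-biomarker machinery: difference-between-mean (DBM) spectra with
# an absolute-coefficient threshold, top-N peaks of the PLS-DA regression
# vector, per-wavenumber one-way ANOVA, and higher/lower intensity calls.

# static annotation lookup (biofingerprint assignments); annotation only,
# matched to the nearest tabulated wavenumber within 30 cm^-1
BAND_ASSIGNMENTS <- data.frame(
  wavenumber = c(1750, 1650, 1550, 1470, 1400, 1260, 1225, 1155, 1080, 1030,
                 970),
  assignment = c("v(C=O) in lipids", "Amide I", "Amide II",
                 "d(CH2) in lipids", "vs(COO-) in amino acids", "Amide III",
                 "vas(PO2-)", "v(C-O-C) in carbohydrates", "vs(PO2-)",
                 "v(C-O) in glycogen", "protein phosphorylation"),
  stringsAsFactors = FALSE
)

lookup_assignment <- function(wavenumber, tol = 30) {
  d <- abs(BAND_ASSIGNMENTS$wavenumber - wavenumber)
  if (min(d) <= tol) BAND_ASSIGNMENTS$assignment[which.min(d)] else NA_character_
}

#' Difference-between-mean (DBM) spectrum
#'
#' Per-wavenumber difference of the two class mean spectra of a
#' preprocessed dataset (`mean(class_pos) - mean(class_neg)`), with marker
#' wavenumbers flagged where the absolute coefficient strictly exceeds the
#' threshold.
#'
#' @param ds a preprocessed `spectral_dataset` containing both classes.
#' @param class_pos,class_neg class codes of the positive (+) and negative
#'   (-) coefficient sides.
#' @param threshold absolute coefficient cut (default 0.01, on the
#'   normalised second-derivative scale).
#' @return an object of class `dbm_spectrum`: list with `wavenumbers`,
#'   `coefficients`, `threshold` and `flagged` (data.frame `wavenumber`,
#'   `coefficient`, `sign`).
#' @export
dbm <- function(ds, class_pos, class_neg, threshold = 0.01) {
  validate_spectral_dataset(ds)
  for (cl in c(class_pos, class_neg))
    if (!any(ds$labels == cl))
      stop("class ", cl, " absent from dataset", call. = FALSE)
  mp <- colMeans(ds$intensities[ds$labels == class_pos, , drop = FALSE])
  mn <- colMeans(ds$intensities[ds$labels == class_neg, , drop = FALSE])
  coef <- mp - mn
  idx <- which(abs(coef) > threshold)
  structure(list(wavenumbers = ds$wavenumbers, coefficients = coef,
                 threshold = threshold,
                 flagged = data.frame(wavenumber = ds$wavenumbers[idx],
                                      coefficient = coef[idx],
                                      sign = sign(coef[idx])),
                 classes = c(positive = class_pos, negative = class_neg)),
            class = "dbm_spectrum")
}

#' Top peaks of a coefficient vector
#'
#' Automatic peak detection on `|coefficients|`: candidates are interior
#' local extrema strictly greater than both neighbours (plateaus count
#' once, at their leftmost point); the `n_peaks` candidates with the
#' largest absolute coefficient are returned, sorted by magnitude
#' (ties by axis position). If fewer candidates exist, all are returned
#' with a warning; if none exist (monotone input), the endpoint with the
#' larger magnitude is used, with a warning.
#'
#' @param coefficients numeric vector (e.g. a PLS-DA regression vector).
#' @param wavenumbers matching axis, length >= 3.
#' @param n_peaks number of peaks sought (default 8).
#' @return data.frame with `wavenumber`, `coefficient`, ordered by
#'   decreasing `|coefficient|`.
#' @export
top_peaks <- function(coefficients, wavenumbers, n_peaks = 8) {
  stopifnot(n_peaks >= 1, length(coefficients) == length(wavenumbers))
  if (length(wavenumbers) < 3)
    stop("axis must have at least 3 points", call. = FALSE)
  a <- abs(coefficients)
  r <- rle(a)
  starts <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  cand <- integer(0)
  for (j in seq_along(r$values)) {      # plateau-aware interior extrema
    if (j == 1 || j == length(r$values)) next
    if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
      cand <- c(cand, starts[j])        # leftmost point of the plateau
  }
  if (!length(cand)) {
    warning("no interior extrema; falling back to the larger endpoint",
            call. = FALSE)
    cand <- if (a[1] >= a[length(a)]) 1L else length(a)
  }
  if (length(cand) < n_peaks)
    warning("only ", length(cand), " peak(s) found (", n_peaks,
            " requested)", call. = FALSE)
  ord <- cand[order(-a[cand], cand)]
  sel <- utils::head(ord, n_peaks)
  data.frame(wavenumber = wavenumbers[sel], coefficient = coefficients[sel])
}

axis_spacing <- function(wavenumbers) {
  if (length(wavenumbers) < 2) return(Inf)
  stats::median(abs(diff(wavenumbers)))
}

lookup_column <- function(ds, wavenumber) {
  d <- abs(ds$wavenumbers - wavenumber)
  j <- which.min(d)
  if (d[j] > axis_spacing(ds$wavenumbers) / 2)
    stop(sprintf("wavenumber %g cm^-1 is off-axis (nearest grid point %g)",
                 wavenumber, ds$wavenumbers[j]), call. = FALSE)
  j
}

#' One-way ANOVA p-value at a single wavenumber
#'
#' Fixed-effects one-way ANOVA F-test of the preprocessed intensity at the
#' given wavenumber across the label groups (individual spectra are the
#' observations by default; `level = "patient"` uses patient means). The
#' wavenumber must match an axis position to within half the axis spacing.
#'
#' @param ds a preprocessed `spectral_dataset`.
#' @param wavenumber position in cm^-1.
#' @param groups optional grouping vector (defaults to `ds$labels`).
#' @param level `"spectrum"` (default) or `"patient"`.
#' @return the ANOVA p-value.
#' @export
marker_anova <- function(ds, wavenumber, groups = NULL,
                         level = c("spectrum", "patient")) {
  validate_spectral_dataset(ds)
  level <- match.arg(level)
  j <- lookup_column(ds, wavenumber)
  if (level == "patient") {
    pm <- patient_means(ds)
    v <- pm$means[, j]
    g <- factor(pm$labels)
  } else {
    v <- ds$intensities[, j]
    g <- factor(if (is.null(groups)) ds$labels else groups)
  }
  if (nlevels(g) < 2 || min(table(g)) < 2)
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  gm <- tapply(v, g, mean)
  ssb <- sum(table(g) * (gm - mean(v))^2)
  if (ssb <= .Machine$double.eps * sum(v^2)) return(1)  # no group effect
  p <- stats::oneway.test(v ~ g, var.equal = TRUE)$p.value
  if (is.nan(p)) p <- 0   # zero within-group variance but distinct means
  p
}

#' Relative-intensity direction at a wavenumber
#'
#' `"up"` iff the mean preprocessed intensity of `class_a` exceeds that of
#' `class_b` at the wavenumber; exact ties return `"down"` with a warning.
#'
#' @param ds a preprocessed `spectral_dataset`.
#' @param wavenumber position in cm^-1 (half-spacing lookup tolerance).
#' @param class_a,class_b class codes.
#' @return `"up"` or `"down"`.
#' @export
intensity_direction <- function(ds, wavenumber, class_a, class_b) {
  validate_spectral_dataset(ds)
  j <- lookup_column(ds, wavenumber)
  ma <- mean(ds$intensities[ds$labels == class_a, j])
  mb <- mean(ds$intensities[ds$labels == class_b, j])
  if (ma == mb) {
    warning("exact tie at ", wavenumber, " cm^-1; reporting 'down'",
            call. = FALSE)
    return("down")
  }
  if (ma > mb) "up" else "down"
}

#' Build a spectral-marker table
#'
#' Composes [top_peaks()] on a coefficient vector — the regression vector
#' of a fitted PLS-DA model, or the coefficients of a [dbm()] spectrum —
#' with [intensity_direction()] (positive vs negative class) and
#' [marker_anova()] at each peak. Significance tags follow the usual
#' convention: `**` for p < 0.001, `*` for p < 0.05. No multiple-testing
#' correction is applied by default; set `fdr = TRUE` to add a
#' Benjamini-Hochberg adjusted column.
#'
#' @param model a fitted `pls_da`, or a `dbm_spectrum` (whose peaks are
#'   the positions of largest absolute mean contrast).
#' @param ds the preprocessed `spectral_dataset` the model/DBM was built
#'   on (same axis); only the model's two classes are used for direction
#'   and ANOVA.
#' @param n_peaks number of marker rows sought (default 8).
#' @param anova_level `"spectrum"` (default) or `"patient"`.
#' @param fdr add a BH-adjusted p-value column (default FALSE).
#' @return an object of class `marker_table`: data.frame with
#'   `wavenumber`, `assignment`, `coefficient`, `direction`, `p_value`,
#'   `significance`, sorted by decreasing `|coefficient|`.
#' @export
build_marker_table <- function(model, ds, n_peaks = 8,
                               anova_level = c("spectrum", "patient"),
                               fdr = FALSE) {
  anova_level <- match.arg(anova_level)
  if (inherits(model, "pls_da")) {
    check_axis(model$wavenumbers, ds$wavenumbers, length(ds$wavenumbers),
               length(model$x_mean))
    coef <- model$regression_vector
    cls <- model$classes
  } else if (inherits(model, "dbm_spectrum")) {
    check_axis(model$wavenumbers, ds$wavenumbers, length(ds$wavenumbers),
               length(model$coefficients))
    coef <- model$coefficients
    cls <- model$classes
  } else {
    stop("model must be a pls_da or a dbm_spectrum", call. = FALSE)
  }
  two <- subset_spectra(ds, labels = unname(cls))
  peaks <- top_peaks(coef, ds$wavenumbers, n_peaks)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    wn <- peaks$wavenumber[i]
    p <- marker_anova(two, wn, level = anova_level)
    data.frame(
      wavenumber = wn,
      assignment = lookup_assignment(wn),
      coefficient = peaks$coefficient[i],
      direction = intensity_direction(two, wn, cls[["positive"]],
                                      cls[["negative"]]),
      p_value = p,
      significance = if (p < 0.001) "**" else if (p < 0.05) "*" else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$coefficient), out$wavenumber), ]
  rownames(out) <- NULL
  if (fdr) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("marker_table", "data.frame")
  out
}
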