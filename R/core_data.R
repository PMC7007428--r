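# Class codes used throughout: G1 (WHO grade I), G2 (WHO grade II),
# G1R (WHO grade I that later recurred).
GRADE_CODES <- c("G1", "G2", "G1R")

#' Construct a spectral dataset
#'
#' The central container of the package: a wavenumber axis, one intensity row
#' per acquired spectrum, and per-spectrum identifiers and class labels.
#' The wavenumber axis is stored in acquisition order (conventionally
#' high-to-low, as spectrometers write it); all downstream stages are
#' direction-agnostic.
#'
#' @param wavenumbers numeric axis in cm^-1, strictly monotonic (either
#'   direction), no duplicates.
#' @param intensities numeric matrix, one row per spectrum, one column per
#'   axis position (absorbance or derivative units).
#' @param spectrum_ids character, unique per row.
#' @param patient_ids character, one per row; all rows of a patient must
#'   share one label.
#' @param labels character, one of `"G1"`, `"G2"`, `"G1R"` per row.
#' @param stage_tag provenance string: `"raw"`, `"truncated"`,
#'   `"derivative"` or `"normalized"`.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumbers, intensities, spectrum_ids,
                             patient_ids, labels, stage_tag = "raw") {
  intensities <- as.matrix(intensities)
  ds <- structure(
    list(
      wavenumbers  = as.numeric(wavenumbers),
      intensities  = intensities,
      spectrum_ids = as.character(spectrum_ids),
      patient_ids  = as.character(patient_ids),
      labels       = as.character(labels),
      stage_tag    = stage_tag
    ),
    class = "spectral_dataset"
  )
  validate_spectral_dataset(ds)
  ds
}

#' Validate a spectral dataset
#'
#' Checks the container invariants: strictly monotonic axis, matching
#' dimensions, unique spectrum ids, per-patient label consistency and a
#' known stage tag. Called by every constructor/transformer; exported for
#' direct use on externally assembled objects.
#'
#' @param ds a `spectral_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_spectral_dataset <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  wn <- ds$wavenumbers
  if (length(wn) < 1 || anyNA(wn))
    stop("wavenumber axis must be non-empty and free of NA", call. = FALSE)
  if (length(wn) > 1) {
    d <- diff(wn)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumber axis must be strictly monotonic (no duplicates)",
           call. = FALSE)
  }
  n <- nrow(ds$intensities)
  if (ncol(ds$intensities) != length(wn))
    stop("intensity matrix must have one column per wavenumber", call. = FALSE)
  if (length(ds$spectrum_ids) != n || length(ds$patient_ids) != n ||
      length(ds$labels) != n)
    stop("spectrum_ids, patient_ids and labels must match the row count",
         call. = FALSE)
  if (anyDuplicated(ds$spectrum_ids))
    stop("spectrum_ids must be unique", call. = FALSE)
  if (!all(ds$labels %in% GRADE_CODES))
    stop("labels must be one of ", paste(GRADE_CODES, collapse = ", "),
         call. = FALSE)
  lab_by_pat <- tapply(ds$labels, ds$patient_ids,
                       function(x) length(unique(x)))
  if (length(lab_by_pat) && any(lab_by_pat > 1))
    stop("all spectra of a patient must share one label; offending patient: ",
         names(lab_by_pat)[which(lab_by_pat > 1)[1]], call. = FALSE)
  if (!ds$stage_tag %in% c("raw", "truncated", "derivative", "normalized"))
    stop("unknown stage_tag: ", ds$stage_tag, call. = FALSE)
  invisible(ds)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d wavenumbers [%g-%g cm^-1], stage '%s'\n",
    nrow(x$intensities), length(x$wavenumbers), rng[1], rng[2], x$stage_tag))
  tab <- table(x$labels[!duplicated(x$patient_ids)])
  cat("  patients per class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of spectra in a dataset
#' @param ds a `spectral_dataset`.
#' @return integer row count.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Subset a spectral dataset
#'
#' Selects rows by class label, patient id, explicit row index, or an
#' arbitrary predicate over (patient_id, label). Row order, the axis and all
#' invariants are preserved; an empty selection is allowed.
#'
#' @param ds a `spectral_dataset`.
#' @param labels optional character vector of class codes to keep.
#' @param patients optional character vector of patient ids to keep.
#' @param rows optional integer/logical row index.
#' @param predicate optional `function(patient_id, label) -> logical`.
#' @return a `spectral_dataset` with the selected rows.
#' @export
subset_spectra <- function(ds, labels = NULL, patients = NULL, rows = NULL,
                           predicate = NULL) {
  validate_spectral_dataset(ds)
  keep <- rep(TRUE, n_spectra(ds))
  if (!is.null(labels))   keep <- keep & ds$labels %in% labels
  if (!is.null(patients)) keep <- keep & ds$patient_ids %in% patients
  if (!is.null(rows)) {
    sel <- rep(FALSE, n_spectra(ds))
    sel[rows] <- TRUE
    keep <- keep & sel
  }
  if (!is.null(predicate))
    keep <- keep & mapply(predicate, ds$patient_ids, ds$labels)
  idx <- which(keep)
  out <- ds
  out$intensities  <- ds$intensities[idx, , drop = FALSE]
  out$spectrum_ids <- ds$spectrum_ids[idx]
  out$patient_ids  <- ds$patient_ids[idx]
  out$labels       <- ds$labels[idx]
  out
}

#' Relabel whole patients
#'
#' Reassigns the class label of every spectrum belonging to the given
#' patients (labels are a per-patient property, so relabelling is only
#' allowed patient-wise). Used e.g. to construct cohorts in which some
#' grade I patients carry a planted recurrence-like spectral profile.
#'
#' @param ds a `spectral_dataset`.
#' @param patients character vector of patient ids present in `ds`.
#' @param new_label a single class code.
#' @return the relabelled `spectral_dataset`.
#' @export
relabel_patients <- function(ds, patients, new_label) {
  validate_spectral_dataset(ds)
  stopifnot(length(new_label) == 1, new_label %in% GRADE_CODES)
  missing <- setdiff(patients, ds$patient_ids)
  if (length(missing))
    stop("unknown patient id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ds$labels[ds$patient_ids %in% patients] <- new_label
  validate_spectral_dataset(ds)
  ds
}

#' Per-patient mean spectra
#'
#' @param ds a `spectral_dataset`.
#' @return a list with `patients` (ids, in first-appearance order), `labels`
#'   (one per patient) and `means` (matrix, one row per patient).
#' @export
patient_means <- function(ds) {
  validate_spectral_dataset(ds)
  pats <- unique(ds$patient_ids)
  m <- t(vapply(pats, function(p) {
    colMeans(ds$intensities[ds$patient_ids == p, , drop = FALSE])
  }, numeric(length(ds$wavenumbers))))
  labs <- ds$labels[match(pats, ds$patient_ids)]
  list(patients = pats, labels = labs, means = m)
}

#' Read spectra from a wide CSV plus metadata sidecar
#'
#' File dialect (documented bit-exactly in the README): the spectra file is
#' comma-separated, first header cell `spectrum_id` followed by the numeric
#' wavenumbers; each subsequent line is a spectrum id followed by one
#' intensity per wavenumber. The metadata sidecar is tab-separated with
#' header `spectrum_id  patient_id  label`.
#'
#' @param path path to the wide CSV spectra file.
#' @param metadata_path path to the TSV metadata sidecar.
#' @return a `spectral_dataset` with `stage_tag = "raw"`.
#' @export
read_spectra <- function(path, metadata_path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty spectra file: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1]))
    stop("ragged rows in spectra file (line ",
         which(widths != widths[1])[1], ")", call. = FALSE)
  header <- fields[[1]]
  wn <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wn))
    stop("non-numeric wavenumber in header of ", path, call. = FALSE)
  if (anyDuplicated(wn))
    stop("duplicate wavenumber value in header of ", path, call. = FALSE)
  body <- fields[-1]
  ids <- vapply(body, `[`, character(1), 1)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(wn))
  if (length(body)) {
    vals <- do.call(rbind, lapply(body, function(f) {
      v <- suppressWarnings(as.numeric(f[-1]))
      if (anyNA(v)) stop("non-numeric intensity for spectrum ", f[1],
                         call. = FALSE)
      v
    }))
  }
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            colClasses = "character")
  need <- c("spectrum_id", "patient_id", "label")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  only_data <- setdiff(ids, meta$spectrum_id)
  only_meta <- setdiff(meta$spectrum_id, ids)
  if (length(only_data))
    stop("spectra missing from metadata: ",
         paste(only_data, collapse = ", "), call. = FALSE)
  if (length(only_meta))
    stop("metadata rows without spectra: ",
         paste(only_meta, collapse = ", "), call. = FALSE)
  m <- meta[match(ids, meta$spectrum_id), ]
  spectral_dataset(wn, vals, ids, m$patient_id, m$label, stage_tag = "raw")
}

#' Write spectra to the wide CSV + TSV dialect read by [read_spectra()]
#'
#' Numeric values are written with `%.10g`, so a write/read round trip is
#' lossless to 10 significant digits.
#'
#' @param ds a `spectral_dataset`.
#' @param path output path for the wide CSV spectra file.
#' @param metadata_path output path for the TSV metadata sidecar.
#' @return invisibly, `NULL`.
#' @export
write_spectra <- function(ds, path, metadata_path) {
  validate_spectral_dataset(ds)
  num <- function(x) formatC(x, format = "g", digits = 10)
  header <- paste(c("spectrum_id", num(ds$wavenumbers)), collapse = ",")
  rows <- character(0)
  if (n_spectra(ds) > 0) {
    rows <- vapply(seq_len(n_spectra(ds)), function(i) {
      paste(c(ds$spectrum_ids[i], num(ds$intensities[i, ])), collapse = ",")
    }, character(1))
  }
  writeLines(c(header, rows), path)
  meta <- data.frame(spectrum_id = ds$spectrum_ids,
                     patient_id = ds$patient_ids,
                     label = ds$labels)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
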