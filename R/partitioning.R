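# Kennard-Stone training/validation split and venetian-blinds
# cross-validation folds, with patient-level grouping by default so that
# replicate spectra of one tissue sample never straddle a split.

#' Kennard-Stone maximin selection
#'
#' Deterministic uniform sample selection: the first two selections are the
#' pair at maximal Euclidean distance; each subsequent selection maximises
#' the minimum distance to the already-selected set. Ties are broken by the
#' smallest row index, making the output stable across runs.
#'
#' @param points numeric matrix, one representative vector per candidate.
#' @param k number of candidates to select (2 <= k <= nrow(points); k = 1
#'   is only allowed when there is a single candidate).
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k <= n)
  if (n == 1) return(1L)
  if (k < 2) stop("k must be >= 2 when more than one candidate exists",
                  call. = FALSE)
  D <- as.matrix(stats::dist(points))
  # initial pair: maximal distance, ties -> lexicographically smallest (i, j)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    mind <- apply(D[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(mind)])   # which.max -> first (lowest index)
  }
  sel
}

#' Venetian-blinds cross-validation folds
#'
#' Interleaved fold assignment: fold j receives the objects at positions
#' j, j + n_splits, j + 2 n_splits, ... The folds are disjoint and
#' exhaustive.
#'
#' @param n_objects number of objects, >= `n_splits`.
#' @param n_splits number of folds (default 10).
#' @return list of integer index vectors, one per fold.
#' @export
venetian_blinds <- function(n_objects, n_splits = 10) {
  if (n_objects < n_splits)
    stop("n_objects must be >= n_splits", call. = FALSE)
  lapply(seq_len(n_splits), function(j) seq(j, n_objects, by = n_splits))
}

#' Kennard-Stone training/validation split of a dataset
#'
#' Runs Kennard-Stone within each class separately — on patient-mean
#' preprocessed spectra at the default patient level, or on individual
#' spectra at spectrum level — and sends the selected units (with all their
#' replicate spectra, at patient level) to the training side. Venetian
#' blinds folds over the training units (in dataset order) are attached for
#' cross-validated component selection.
#'
#' @param ds a (preprocessed) `spectral_dataset`.
#' @param train_fraction fraction of units per class selected for training
#'   (default 0.7; counts are rounded to the nearest integer).
#' @param level `"patient"` (default) or `"spectrum"`.
#' @param n_splits venetian-blinds fold count (default 10).
#' @return an object of class `partition`: list with `train_patients`,
#'   `validation_patients`, `train_rows`, `validation_rows`, `cv_folds`
#'   (row indices into `ds`, partitioning `train_rows`), `scheme`,
#'   `cv_scheme`, `n_splits`, `level`.
#' @export
split_dataset <- function(ds, train_fraction = 0.7,
                          level = c("patient", "spectrum"), n_splits = 10) {
  validate_spectral_dataset(ds)
  level <- match.arg(level)
  stopifnot(train_fraction > 0, train_fraction <= 1)
  if (train_fraction == 1)
    warning("train_fraction = 1: validation set is empty", call. = FALSE)

  if (level == "patient") {
    pm <- patient_means(ds)
    train_units <- character(0)
    for (cl in unique(pm$labels)) {
      idx <- which(pm$labels == cl)
      if (length(idx) < 2)
        stop("class ", cl, " has a single patient; cannot split", call. = FALSE)
      k <- round(train_fraction * length(idx))
      k <- max(min(k, length(idx)), if (length(idx) > 1) 2 else 1)
      sel <- kennard_stone(pm$means[idx, , drop = FALSE], k)
      train_units <- c(train_units, pm$patients[idx][sel])
    }
    train_rows <- which(ds$patient_ids %in% train_units)
    validation_rows <- setdiff(seq_len(n_spectra(ds)), train_rows)
    train_patients <- unique(ds$patient_ids[train_rows])
    validation_patients <- setdiff(unique(ds$patient_ids), train_patients)
    # folds over training patients in dataset order, expanded to spectra
    fold_pats <- venetian_blinds(length(train_patients), n_splits)
    cv_folds <- lapply(fold_pats, function(f) {
      which(ds$patient_ids %in% train_patients[f])
    })
  } else {
    train_rows <- integer(0)
    for (cl in unique(ds$labels)) {
      idx <- which(ds$labels == cl)
      if (length(idx) < 2)
        stop("class ", cl, " has a single spectrum; cannot split",
             call. = FALSE)
      k <- max(round(train_fraction * length(idx)), 2)
      sel <- kennard_stone(ds$intensities[idx, , drop = FALSE],
                           min(k, length(idx)))
      train_rows <- c(train_rows, idx[sel])
    }
    train_rows <- sort(train_rows)
    validation_rows <- setdiff(seq_len(n_spectra(ds)), train_rows)
    train_patients <- unique(ds$patient_ids[train_rows])
    validation_patients <- unique(ds$patient_ids[validation_rows])
    cv_folds <- lapply(venetian_blinds(length(train_rows), n_splits),
                       function(f) train_rows[f])
  }
  structure(list(train_patients = train_patients,
                 validation_patients = validation_patients,
                 train_rows = sort(train_rows),
                 validation_rows = sort(validation_rows),
                 cv_folds = cv_folds,
                 scheme = "kennard_stone", cv_scheme = "venetian_blinds",
                 n_splits = n_splits, level = level),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf(
    "<partition> %s-level Kennard-Stone: %d train / %d validation patients; %d/%d spectra; %d venetian-blinds folds\n",
    x$level, length(x$train_patients), length(x$validation_patients),
    length(x$train_rows), length(x$validation_rows), x$n_splits))
  invisible(x)
}
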