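# Fingerprint truncation, Savitzky-Golay derivative filtering and vector
# normalisation — the fixed preprocessing chain of the workflow.

#' Preprocessing parameters
#'
#' @param fp_lo,fp_hi fingerprint truncation bounds in cm^-1 (closed
#'   interval; defaults 900 and 1800).
#' @param window odd Savitzky-Golay window length in points (default 7).
#' @param polyorder polynomial order of the local fit (default 2).
#' @param deriv derivative order (default 2), must not exceed `polyorder`.
#' @param normalisation only `"vector"` (Euclidean) is supported.
#' @return a validated list of class `preprocess_params`.
#' @export
preprocess_params <- function(fp_lo = 900, fp_hi = 1800, window = 7,
                              polyorder = 2, deriv = 2,
                              normalisation = "vector") {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  stopifnot(window >= polyorder + 1, deriv <= polyorder, fp_lo < fp_hi,
            normalisation == "vector")
  structure(list(fp_lo = fp_lo, fp_hi = fp_hi, window = window,
                 polyorder = polyorder, deriv = deriv,
                 normalisation = normalisation),
            class = "preprocess_params")
}

#' Truncate a dataset to a wavenumber interval
#'
#' Retains axis positions with `fp_lo <= wavenumber <= fp_hi` (closed on
#' both ends), preserving the axis direction.
#'
#' @param ds a `spectral_dataset`.
#' @param fp_lo,fp_hi interval bounds in cm^-1.
#' @return truncated `spectral_dataset` with `stage_tag = "truncated"`.
#' @export
truncate_fingerprint <- function(ds, fp_lo = 900, fp_hi = 1800) {
  validate_spectral_dataset(ds)
  stopifnot(fp_lo < fp_hi)
  keep <- ds$wavenumbers >= fp_lo & ds$wavenumbers <= fp_hi
  if (!any(keep))
    stop(sprintf("interval [%g, %g] does not intersect the axis",
                 fp_lo, fp_hi), call. = FALSE)
  ds$wavenumbers <- ds$wavenumbers[keep]
  ds$intensities <- ds$intensities[, keep, drop = FALSE]
  ds$stage_tag <- "truncated"
  ds
}

#' Savitzky-Golay convolution kernel
#'
#' Least-squares polynomial-fit derivative estimator at the window centre:
#' a polynomial of order `polyorder` is fitted over the `window` symmetric
#' offsets and its `deriv`-th derivative evaluated at the centre, scaled by
#' `spacing^(-deriv)`. For `deriv = 0` the coefficients sum to 1; for even
#' derivative orders the kernel is symmetric.
#'
#' @param window odd window length in points.
#' @param polyorder local polynomial order.
#' @param deriv derivative order.
#' @param spacing axis point spacing (its absolute value is used: even
#'   derivatives are direction-agnostic and the workflow only uses
#'   `deriv` 0 or 2).
#' @return numeric kernel of length `window`; the filtered value at point i
#'   is `sum(kernel * y[i + (-h:h)])`.
#' @export
sg_kernel <- function(window, polyorder, deriv, spacing = 1) {
  p <- preprocess_params(window = window, polyorder = polyorder,
                         deriv = deriv)   # reuse validation
  h <- (window - 1) %/% 2
  A <- outer(-h:h, 0:polyorder, `^`)
  # row of the pseudo-inverse picking the deriv-th polynomial coefficient,
  # times deriv! to turn the coefficient into a derivative
  pinv <- solve(crossprod(A), t(A))
  pinv[deriv + 1, ] * factorial(deriv) / abs(spacing)^deriv
}

# full SG filter matrix (n x n): interior rows are the centred kernel,
# boundary rows evaluate the polynomial fitted over the nearest fully
# interior window at the edge offsets (same-length output).
sg_filter_matrix <- function(n, window, polyorder, deriv, spacing) {
  h <- (window - 1) %/% 2
  if (n < window) stop("fewer columns than the filter window", call. = FALSE)
  A <- outer(-h:h, 0:polyorder, `^`)
  pinv <- solve(crossprod(A), t(A))                 # (polyorder+1) x window
  # derivative-evaluation row at offset t: sum_k a_k k!/(k-deriv)! t^(k-deriv)
  eval_row <- function(t) {
    k <- 0:polyorder
    coef <- ifelse(k >= deriv,
                   factorial(k) / factorial(pmax(k - deriv, 0)) *
                     t^pmax(k - deriv, 0), 0)
    as.numeric(coef %*% pinv) / abs(spacing)^deriv
  }
  M <- matrix(0, n, n)
  centre <- eval_row(0)
  for (i in (h + 1):(n - h)) M[i, (i - h):(i + h)] <- centre
  for (i in seq_len(h)) {                           # left edge, window 1..w
    M[i, 1:window] <- eval_row(i - (h + 1))
    M[n - i + 1, (n - window + 1):n] <- eval_row((h + 1) - i)
  }
  M
}

#' Savitzky-Golay second-derivative filtering
#'
#' Applies the derivative filter along the wavenumber axis of every
#' spectrum. Interior points use centred windows; edge points evaluate the
#' polynomial fitted over the nearest fully interior window at the edge
#' offsets, so the output keeps the input length (set `edges = "trim"` to
#' drop the half-window at each end instead).
#'
#' @param ds a `spectral_dataset`.
#' @param params a `preprocess_params` (window/polyorder/deriv are used).
#' @param edges `"extend"` (default, same-length output) or `"trim"`.
#' @return filtered `spectral_dataset` with `stage_tag = "derivative"`.
#' @export
second_derivative <- function(ds, params = preprocess_params(),
                              edges = c("extend", "trim")) {
  validate_spectral_dataset(ds)
  edges <- match.arg(edges)
  n <- length(ds$wavenumbers)
  if (n < params$window)
    stop("dataset has fewer wavenumbers than the filter window", call. = FALSE)
  spacing <- if (n > 1) abs(ds$wavenumbers[2] - ds$wavenumbers[1]) else 1
  M <- sg_filter_matrix(n, params$window, params$polyorder, params$deriv,
                        spacing)
  out <- ds
  out$intensities <- ds$intensities %*% t(M)
  if (edges == "trim") {
    h <- (params$window - 1) %/% 2
    keep <- (h + 1):(n - h)
    out$wavenumbers <- out$wavenumbers[keep]
    out$intensities <- out$intensities[, keep, drop = FALSE]
  }
  out$stage_tag <- "derivative"
  out
}

#' Vector (Euclidean) normalisation
#'
#' Divides every spectrum by its Euclidean norm so each row of the output
#' has unit length.
#'
#' @param ds a `spectral_dataset`.
#' @return normalised `spectral_dataset` with `stage_tag = "normalized"`.
#' @export
vector_normalize <- function(ds) {
  validate_spectral_dataset(ds)
  nrm <- sqrt(rowSums(ds$intensities^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stop("degenerate all-zero spectrum: ", ds$spectrum_ids[bad[1]],
         call. = FALSE)
  ds$intensities <- ds$intensities / nrm
  ds$stage_tag <- "normalized"
  ds
}

#' Full preprocessing chain
#'
#' Truncation to the fingerprint window, Savitzky-Golay second-derivative
#' filtering, then vector normalisation — in that order. The composition is
#' invariant to positive multiplicative gains and to constant or linear
#' additive baselines on the input spectra.
#'
#' @param ds a raw `spectral_dataset`.
#' @param params a `preprocess_params`.
#' @return preprocessed `spectral_dataset` with `stage_tag = "normalized"`.
#' @export
preprocess <- function(ds, params = preprocess_params()) {
  ds <- truncate_fingerprint(ds, params$fp_lo, params$fp_hi)
  ds <- second_derivative(ds, params)
  vector_normalize(ds)
}
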