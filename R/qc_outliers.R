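# PCA-model-based Hotelling T2 versus Q-residual outlier screening.

#' Hotelling T2 / Q-residual outlier test
#'
#' Fits a PCA model to the mean-centred preprocessed spectra and computes,
#' per spectrum, the within-model Hotelling statistic
#' `T2_i = sum_k t_ik^2 / lambda_k` over the retained components and the
#' off-model residual `Q_i` (squared reconstruction residual norm). The T2
#' control limit uses the F-distribution scaling
#' `k (n - 1) / (n - k) * F(1 - alpha; k, n - k)`; the Q limit uses the
#' Jackson-Mudholkar approximation from the discarded eigenvalues. A
#' spectrum is flagged only when it exceeds BOTH limits (conservative AND
#' rule); removal is left to the caller — the report is diagnostic only.
#'
#' @param ds a preprocessed `spectral_dataset`.
#' @param n_components number of PCs; if `NULL`, the smallest number
#'   reaching `evr` cumulative explained variance.
#' @param alpha confidence level of both limits (default 0.05).
#' @param evr cumulative explained-variance target used when
#'   `n_components` is `NULL` (default 0.95).
#' @return an object of class `outlier_report`: data.frame
#'   (`spectrum_id`, `t2`, `q`, `flag`) plus attributes `t2_limit`,
#'   `q_limit`, `n_components`, `alpha`.
#' @export
t2q_test <- function(ds, n_components = NULL, alpha = 0.05, evr = 0.95) {
  validate_spectral_dataset(ds)
  stopifnot(alpha > 0, alpha < 1)
  X <- ds$intensities
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  lambda <- sv$d^2 / (n - 1)                    # score variances per PC
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (is.null(n_components)) {
    cum <- cumsum(lambda) / sum(lambda)
    n_components <- min(which(cum >= evr), rank)
  }
  k <- n_components
  if (k >= min(n, ncol(X)))
    stop("n_components must be < min(n spectra, n wavenumbers)", call. = FALSE)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  t2 <- rowSums(sweep(scores^2, 2, lambda[seq_len(k)], `/`))
  recon <- scores %*% t(sv$v[, seq_len(k), drop = FALSE])
  q <- rowSums((Xc - recon)^2)
  t2_limit <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  disc <- lambda[seq_len(rank)][-seq_len(min(k, rank))]
  q_limit <- jackson_mudholkar_limit(disc, alpha)
  flag <- t2 > t2_limit & q > q_limit
  structure(
    data.frame(spectrum_id = ds$spectrum_ids, t2 = t2, q = q, flag = flag,
               stringsAsFactors = FALSE),
    t2_limit = t2_limit, q_limit = q_limit, n_components = k, alpha = alpha,
    class = c("outlier_report", "data.frame")
  )
}

# Q control limit from the eigenvalues discarded by the PCA model.
# With no residual subspace there is no off-model distance to police, so
# the limit degenerates to +Inf (nothing can be a Q outlier).
jackson_mudholkar_limit <- function(discarded_eigenvalues, alpha) {
  th1 <- sum(discarded_eigenvalues)
  th2 <- sum(discarded_eigenvalues^2)
  th3 <- sum(discarded_eigenvalues^3)
  if (th1 <= 0 || th2 <= 0) return(Inf)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 == 0) return(Inf)
  ca <- stats::qnorm(1 - alpha)
  base <- ca * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2
  if (base <= 0) return(Inf)
  th1 * base^(1 / h0)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %d spectra, %d PCs, alpha = %g; %d flagged (T2 > %.3g AND Q > %.3g)\n",
    nrow(x), attr(x, "n_components"), attr(x, "alpha"), sum(x$flag),
    attr(x, "t2_limit"), attr(x, "q_limit")))
  invisible(x)
}
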