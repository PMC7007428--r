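# The two discriminant learners: PCA-LDA (PCA scores + pooled-covariance
# Mahalanobis assignment, equal class priors) and PLS-DA (NIPALS PLS1 on a
# +/-1-coded response, thresholded at 0), plus cross-validated component
# selection with a one-standard-error tie rule.

#' Principal component analysis of a spectra matrix
#'
#' SVD-based PCA on the column-mean-centred matrix. Scores are
#' `centred X %*% loadings`; eigenvalues are the score variances
#' `d^2 / (n - 1)`; explained variance is reported as a percentage of the
#' total.
#'
#' @param X numeric matrix (spectra in rows).
#' @param k number of components, at most the rank of the centred matrix.
#' @return list with `grand_mean`, `loadings` (p x k, orthonormal columns),
#'   `scores` (n x k), `eigenvalues`, `explained_variance` (percent, per
#'   retained PC).
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  grand_mean <- colMeans(X)
  Xc <- sweep(X, 2, grand_mean)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d, 0) * 1e-10)
  if (k > rank) stop("k exceeds the rank of the centred matrix", call. = FALSE)
  idx <- seq_len(k)
  list(grand_mean = grand_mean,
       loadings = sv$v[, idx, drop = FALSE],
       scores = sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], k, k),
       eigenvalues = sv$d[idx]^2 / (n - 1),
       explained_variance = 100 * sv$d[idx]^2 / sum(sv$d^2))
}

#' Fit a PCA-LDA model
#'
#' Reduces the spectra to `k` principal components and builds a two-class
#' linear discriminant in score space: per-class score means plus the
#' pooled within-class covariance. Prediction assigns by smaller
#' Mahalanobis distance with equal class priors. A near-singular pooled
#' covariance is ridge-regularised (`1e-8 * trace / k` on the diagonal)
#' with a warning.
#'
#' @param X numeric matrix of preprocessed spectra (rows).
#' @param labels class code per row; exactly two distinct classes, each
#'   with >= 2 rows.
#' @param k number of principal components.
#' @param positive_class the class coded positive by the discriminant
#'   score; defaults to the first label encountered.
#' @param wavenumbers optional axis stored for consistency checks at
#'   prediction time.
#' @return an object of class `pca_lda`.
#' @export
fit_pca_lda <- function(X, labels, k, positive_class = NULL,
                        wavenumbers = NULL) {
  X <- as.matrix(X)
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly two classes required", call. = FALSE)
  if (is.null(positive_class)) positive_class <- cls[1]
  stopifnot(positive_class %in% cls)
  negative_class <- setdiff(cls, positive_class)
  if (min(table(labels)) < 2)
    stop("each class needs >= 2 spectra", call. = FALSE)
  pca <- fit_pca(X, k)
  lda <- lda_in_scores(pca$scores, labels, positive_class, negative_class)
  structure(list(grand_mean = pca$grand_mean, loadings = pca$loadings,
                 eigenvalues = pca$eigenvalues,
                 explained_variance = pca$explained_variance, n_pcs = k,
                 class_means_scores = lda$means,
                 pooled_covariance_scores = lda$pool,
                 classes = c(positive = positive_class,
                             negative = negative_class),
                 wavenumbers = wavenumbers),
            class = "pca_lda")
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# class means and pooled within-class covariance in score space, with
# ridge regularisation when near-singular
lda_in_scores <- function(scores, labels, positive_class, negative_class) {
  k <- ncol(scores)
  pool <- matrix(0, k, k)
  means <- list()
  for (cl in c(positive_class, negative_class)) {
    s <- scores[labels == cl, , drop = FALSE]
    means[[cl]] <- colMeans(s)
    pool <- pool + crossprod(sweep(s, 2, means[[cl]])) # (n_c - 1) * S_c
  }
  pool <- pool / (nrow(scores) - 2)
  if (rcond_sym(pool) < 1e-10) {
    warning("near-singular pooled covariance; applying ridge regularisation",
            call. = FALSE)
    pool <- pool + diag(1e-8 * sum(diag(pool)) / k, k)
  }
  list(means = means, pool = pool)
}

# Mahalanobis classification in score space; returns labels and signed score
mahalanobis_assign <- function(scores, means, pool, positive_class,
                               negative_class) {
  Sinv <- solve(pool)
  d2 <- function(cl) {
    d <- sweep(scores, 2, means[[cl]])
    rowSums((d %*% Sinv) * d)
  }
  score <- d2(negative_class) - d2(positive_class)
  list(labels = ifelse(score >= 0, positive_class, negative_class),
       scores = score)
}

# NIPALS PLS1 up to k_max components on pre-centred data; returns the
# weight/loading history so any truncation k <= k_max can be assembled
nipals_pls1 <- function(E, f, k_max) {
  p <- ncol(E)
  ssx <- sum(E^2)
  W <- P <- matrix(0, p, k_max)
  q <- numeric(k_max)
  evar <- numeric(k_max)
  for (a in seq_len(k_max)) {
    w <- crossprod(E, f)                 # X'y direction
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stop("n_lvs exceeds the effective rank of the data", call. = FALSE)
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pl <- crossprod(E, t) / tt
    q[a] <- sum(f * t) / tt
    E <- E - t %*% t(pl)
    W[, a] <- w
    P[, a] <- pl
    evar[a] <- 100 * tt * sum(pl^2) / ssx
  }
  list(W = W, P = P, q = q, evar = evar)
}

pls_regression_vector <- function(nip, k) {
  W <- nip$W[, seq_len(k), drop = FALSE]
  P <- nip$P[, seq_len(k), drop = FALSE]
  as.numeric(W %*% solve(crossprod(P, W), nip$q[seq_len(k)]))
}

#' Predict with a PCA-LDA model
#'
#' Projects new spectra onto the training loadings and assigns each to the
#' class with smaller Mahalanobis distance under the pooled score-space
#' covariance. The signed discriminant score is
#' `D2(negative) - D2(positive)`, so larger means more positive-like; ties
#' (score 0) go to the positive class.
#'
#' @param model a `pca_lda`.
#' @param X numeric matrix of spectra on the training axis.
#' @param wavenumbers optional axis of `X`, checked against the model's.
#' @return list with `labels` (character) and `scores` (numeric).
#' @export
predict_pca_lda <- function(model, X, wavenumbers = NULL) {
  X <- as.matrix(X)
  check_axis(model$wavenumbers, wavenumbers, ncol(X),
             length(model$grand_mean))
  sc <- sweep(X, 2, model$grand_mean) %*% model$loadings
  mahalanobis_assign(sc, model$class_means_scores,
                     model$pooled_covariance_scores,
                     model$classes[["positive"]], model$classes[["negative"]])
}

check_axis <- function(model_axis, new_axis, p_new, p_model) {
  if (p_new != p_model)
    stop("axis mismatch: model has ", p_model, " wavenumbers, data has ",
         p_new, call. = FALSE)
  if (!is.null(model_axis) && !is.null(new_axis) &&
      !isTRUE(all.equal(model_axis, new_axis)))
    stop("axis mismatch: wavenumber grids differ", call. = FALSE)
  invisible(NULL)
}

#' Fit a PLS-DA model (NIPALS PLS1, +/-1-coded response)
#'
#' The class response is coded +1 for `positive_class` and -1 otherwise;
#' X and y are mean-centred and latent variables extracted by NIPALS with
#' deflation of X per component. The regression vector is assembled as
#' `W (P' W)^-1 q`, and prediction thresholds the continuous response at 0.
#'
#' @param X numeric matrix of preprocessed spectra (rows).
#' @param labels class code per row; exactly two distinct classes.
#' @param n_lvs number of latent variables, at most the rank of centred X.
#' @param positive_class class coded +1; defaults to the first label.
#' @param wavenumbers optional axis stored for consistency checks.
#' @return an object of class `pls_da` with `x_mean`, `y_mean`, `weights`,
#'   `x_loadings`, `y_loadings`, `regression_vector`, `n_lvs`,
#'   `x_explained_variance` (percent per LV), `threshold`, `classes`.
#' @export
fit_pls_da <- function(X, labels, n_lvs, positive_class = NULL,
                       wavenumbers = NULL) {
  X <- as.matrix(X)
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly two classes required", call. = FALSE)
  if (is.null(positive_class)) positive_class <- cls[1]
  stopifnot(positive_class %in% cls)
  y <- ifelse(labels == positive_class, 1, -1)
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  nip <- nipals_pls1(sweep(X, 2, x_mean), y - y_mean, n_lvs)
  B <- pls_regression_vector(nip, n_lvs)
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = nip$W,
                 x_loadings = nip$P, y_loadings = nip$q,
                 regression_vector = B, n_lvs = n_lvs,
                 x_explained_variance = nip$evar, threshold = 0,
                 classes = c(positive = positive_class,
                             negative = setdiff(cls, positive_class)),
                 wavenumbers = wavenumbers),
            class = "pls_da")
}

#' Predict with a PLS-DA model
#'
#' The continuous response of a spectrum x is
#' `(x - x_mean) . regression_vector + y_mean`; the label is the positive
#' class iff the response is at or above the threshold (default 0).
#'
#' @param model a `pls_da`.
#' @param X numeric matrix of spectra on the training axis.
#' @param wavenumbers optional axis of `X`, checked against the model's.
#' @return list with `labels` (character) and `scores` (continuous
#'   responses).
#' @export
predict_pls_da <- function(model, X, wavenumbers = NULL) {
  X <- as.matrix(X)
  check_axis(model$wavenumbers, wavenumbers, ncol(X), length(model$x_mean))
  resp <- as.numeric(sweep(X, 2, model$x_mean) %*% model$regression_vector) +
    model$y_mean
  labels <- ifelse(resp >= model$threshold, model$classes[["positive"]],
                   model$classes[["negative"]])
  list(labels = labels, scores = resp)
}

#' Cross-validated component selection
#'
#' Computes venetian-blinds cross-validation accuracy for component counts
#' 1..k_max and chooses the smallest count whose mean CV accuracy is within
#' one standard error of the maximum (the one-standard-error rule). Folds
#' containing a single class are skipped with a warning.
#'
#' @param X numeric matrix of training spectra.
#' @param labels class code per row.
#' @param folds list of row-index vectors into `X` (e.g. from
#'   [split_dataset()], re-indexed to the training matrix, or
#'   [venetian_blinds()]).
#' @param k_max largest component count to try.
#' @param model_kind `"pcalda"` or `"plsda"`.
#' @param positive_class forwarded to the fit functions.
#' @return an object of class `fit_report`: list with
#'   `n_components_chosen` and `cv_accuracy_by_k` (data.frame `k`,
#'   `mean_accuracy`, `se`).
#' @export
select_components <- function(X, labels, folds, k_max,
                              model_kind = c("pcalda", "plsda"),
                              positive_class = NULL) {
  model_kind <- match.arg(model_kind)
  X <- as.matrix(X)
  stopifnot(k_max >= 1)
  usable <- vapply(folds, function(f) {
    length(unique(labels[-f])) == 2 && length(f) > 0
  }, logical(1))
  if (!all(usable))
    warning(sum(!usable), " degenerate fold(s) skipped", call. = FALSE)
  folds <- folds[usable]
  acc <- matrix(NA_real_, nrow = length(folds), ncol = k_max)
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    Xtr <- X[-f, , drop = FALSE]; ltr <- labels[-f]
    Xte <- X[f, , drop = FALSE];  lte <- labels[f]
    cls <- unique(ltr)
    pos <- if (is.null(positive_class)) cls[1] else positive_class
    neg <- setdiff(cls, pos)
    if (model_kind == "pcalda") {
      # one SVD per fold; LDA rebuilt per truncation k
      mu <- colMeans(Xtr)
      sv <- svd(sweep(Xtr, 2, mu))
      rank <- sum(sv$d > max(sv$d, 0) * 1e-10)
      sc_tr <- sv$u %*% diag(sv$d, length(sv$d), length(sv$d))
      sc_te <- sweep(Xte, 2, mu) %*% sv$v
      for (k in seq_len(min(k_max, rank))) {
        lda <- try(suppressWarnings(
          lda_in_scores(sc_tr[, seq_len(k), drop = FALSE], ltr, pos, neg)),
          silent = TRUE)
        if (inherits(lda, "try-error")) next
        pred <- mahalanobis_assign(sc_te[, seq_len(k), drop = FALSE],
                                   lda$means, lda$pool, pos, neg)
        acc[i, k] <- mean(pred$labels == lte)
      }
    } else {
      y <- ifelse(ltr == pos, 1, -1)
      x_mean <- colMeans(Xtr)
      nip <- try(nipals_pls1(sweep(Xtr, 2, x_mean), y - mean(y), k_max),
                 silent = TRUE)
      if (inherits(nip, "try-error")) next
      Ec <- sweep(Xte, 2, x_mean)
      for (k in seq_len(k_max)) {
        resp <- as.numeric(Ec %*% pls_regression_vector(nip, k)) + mean(y)
        acc[i, k] <- mean(ifelse(resp >= 0, pos, neg) == lte)
      }
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  se <- apply(acc, 2, function(a) {
    a <- a[!is.na(a)]
    if (length(a) < 2) 0 else stats::sd(a) / sqrt(length(a))
  })
  best <- which.max(mean_acc)
  chosen <- min(which(mean_acc >= mean_acc[best] - se[best]))
  structure(list(n_components_chosen = chosen,
                 cv_accuracy_by_k = data.frame(k = seq_len(k_max),
                                               mean_accuracy = mean_acc,
                                               se = se)),
            class = "fit_report")
}
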