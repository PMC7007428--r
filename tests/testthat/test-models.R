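test_that("PCA basics: rank-1 variance, orthogonal scores, reconstruction", {
  set.seed(1)
  u <- rnorm(12); v <- rnorm(6)
  rank1 <- outer(u, v)
  pca1 <- fit_pca(rank1, 1)
  expect_equal(pca1$explained_variance[1], 100, tolerance = 1e-8)

  X <- matrix(rnorm(20 * 6), 20)
  pca <- fit_pca(X, 6)
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)            # orthogonal scores
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(recon, sweep(X, 2, colMeans(X)), tolerance = 1e-10,
               ignore_attr = TRUE)                      # full-rank identity
  expect_error(fit_pca(rank1, 3), "rank")
})

test_that("PCA-LDA separates blobs, is chance-level on nulls and when the
           discriminant direction is discarded", {
  set.seed(2)
  # two well-separated blobs in 3-D
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, 0), n), matrix(rnorm(n * 3, 8), n))
  lab <- rep(c("G1", "G2"), each = n)
  m <- fit_pca_lda(X, lab, 2, positive_class = "G2")
  expect_equal(mean(predict_pca_lda(m, X)$labels == lab), 1)

  # identical class distributions -> held-out accuracy near 1/2
  Xn <- matrix(rnorm(2 * n * 5), 2 * n)
  mn <- fit_pca_lda(Xn[1:60, ], lab[1:60], 3, positive_class = "G2")
  held <- predict_pca_lda(mn, Xn[61:80, ])
  expect_lt(mean(held$labels == lab[61:80]), 0.8)

  # class difference orthogonal to PC1: k = 1 is blind to it
  set.seed(3)
  big <- rnorm(200, sd = 20)              # dominant shared direction
  small <- c(rnorm(100, -2, 0.5), rnorm(100, 2, 0.5))  # class signal
  Xc <- cbind(big, small, rnorm(200, sd = 0.5))
  labc <- rep(c("G1", "G2"), each = 100)
  m1 <- fit_pca_lda(Xc, labc, 1, positive_class = "G2")
  acc1 <- mean(predict_pca_lda(m1, Xc)$labels == labc)
  expect_lt(abs(acc1 - 0.5), 0.15)
  m2 <- fit_pca_lda(Xc, labc, 2, positive_class = "G2")
  expect_gt(mean(predict_pca_lda(m2, Xc)$labels == labc), 0.95)
})

test_that("Mahalanobis assignment agrees with closed-form two-class LDA", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 30; p <- 4
    X <- rbind(matrix(rnorm(n * p, 0), n), matrix(rnorm(n * p, 1.2), n))
    lab <- rep(c("G1", "G2"), each = n)
    m <- fit_pca_lda(X, lab, p, positive_class = "G2")
    pred <- predict_pca_lda(m, X)

    # closed-form: w = S^-1 (mu+ - mu-), threshold at the pooled midpoint
    mu_p <- colMeans(X[lab == "G2", ]); mu_n <- colMeans(X[lab == "G1", ])
    S <- (cov(X[lab == "G2", ]) * (n - 1) +
          cov(X[lab == "G1", ]) * (n - 1)) / (2 * n - 2)
    w <- solve(S, mu_p - mu_n)
    z <- X %*% w - sum(w * (mu_p + mu_n)) / 2
    expect_equal(pred$labels, ifelse(z >= 0, "G2", "G1"),
                 ignore_attr = TRUE, label = paste("seed", seed))
  }
})

test_that("PCA-LDA matches MASS::lda with equal priors", {
  skip_if_not_installed("MASS")
  set.seed(11)
  n <- 25; p <- 5
  X <- rbind(matrix(rnorm(n * p, 0), n), matrix(rnorm(n * p, 1), n))
  lab <- rep(c("G1", "G2"), each = n)
  ours <- predict_pca_lda(fit_pca_lda(X, lab, p, positive_class = "G2"), X)
  ref <- MASS::lda(X, grouping = lab, prior = c(0.5, 0.5))
  expect_equal(ours$labels, as.character(predict(ref, X)$class),
               ignore_attr = TRUE)
})

test_that("ties at the decision boundary go to the positive class", {
  X <- rbind(c(-1, 0), c(-1.1, 0.3), c(-0.9, -0.2),
             c(1, 0), c(1.1, -0.3), c(0.9, 0.2))
  lab <- rep(c("G1", "G2"), each = 3)
  m <- fit_pca_lda(X, lab, 2, positive_class = "G2")
  mid <- (colMeans(X[1:3, ]) + colMeans(X[4:6, ])) / 2
  pred <- predict_pca_lda(m, rbind(mid))
  expect_lt(abs(pred$scores), 1e-9)
  expect_equal(pred$labels, "G2", ignore_attr = TRUE)
})

test_that("PLS-DA: first weight is the X'y direction; full rank equals
           least squares; label swap negates the coefficients", {
  set.seed(4)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n)
  lab <- rep(c("G1", "G2"), 15)
  y <- ifelse(lab == "G2", 1, -1)

  m1 <- fit_pls_da(X, lab, 1, positive_class = "G2")
  xc <- sweep(X, 2, colMeans(X))
  w_ref <- crossprod(xc, y - mean(y))
  cosine <- sum(m1$weights[, 1] * w_ref) /
    sqrt(sum(m1$weights[, 1]^2) * sum(w_ref^2))
  expect_equal(cosine, 1, tolerance = 1e-10)

  mfull <- fit_pls_da(X, lab, p, positive_class = "G2")
  ls <- lm(y ~ X)
  expect_equal(predict_pls_da(mfull, X)$scores, unname(fitted(ls)),
               tolerance = 1e-6)

  mswap <- fit_pls_da(X, lab, 3, positive_class = "G1")
  m3 <- fit_pls_da(X, lab, 3, positive_class = "G2")
  expect_equal(mswap$regression_vector, -m3$regression_vector,
               tolerance = 1e-10)
  expect_equal(predict_pls_da(mswap, X)$labels, predict_pls_da(m3, X)$labels)
})

test_that("PLS-DA responses are linear and centroids side correctly", {
  set.seed(5)
  n <- 20; p <- 5
  X <- rbind(matrix(rnorm(n * p, 0), n), matrix(rnorm(n * p, 2), n))
  lab <- rep(c("G1", "G2"), each = n)
  m <- fit_pls_da(X, lab, 2, positive_class = "G2")
  # training positive centroid responds positive
  cen <- colMeans(X[lab == "G2", , drop = FALSE])
  expect_gt(predict_pls_da(m, rbind(cen))$scores, 0)
  # adding eps * B strictly increases the response
  x0 <- X[1, ]
  r0 <- predict_pls_da(m, rbind(x0))$scores
  r1 <- predict_pls_da(m, rbind(x0 + 0.1 * m$regression_vector))$scores
  expect_gt(r1, r0)
  # response exactly at the threshold -> positive class by the tie rule
  m_tie <- m; m_tie$threshold <- r0
  expect_equal(predict_pls_da(m_tie, rbind(x0))$labels, "G2",
               ignore_attr = TRUE)
})

test_that("both learners are invariant to wavenumber permutation", {
  set.seed(6)
  n <- 24; p <- 8
  X <- rbind(matrix(rnorm(n * p, 0), n), matrix(rnorm(n * p, 1), n))
  lab <- rep(c("G1", "G2"), each = n)
  perm <- sample(p)
  mp <- fit_pls_da(X[, perm], lab, 3, positive_class = "G2")
  m0 <- fit_pls_da(X, lab, 3, positive_class = "G2")
  expect_equal(mp$regression_vector, m0$regression_vector[perm],
               tolerance = 1e-10)
  l0 <- predict_pca_lda(fit_pca_lda(X, lab, 4, positive_class = "G2"), X)
  lp <- predict_pca_lda(fit_pca_lda(X[, perm], lab, 4, positive_class = "G2"),
                        X[, perm])
  expect_equal(lp$labels, l0$labels)
})

test_that("training accuracy is non-decreasing in component count", {
  sd0 <- small_study(class_sizes = c(G1 = 8, G2 = 6), replicates = 4,
                     effect_magnitude = 0.08)
  ds <- generate_cohort(sd0$design, sd0$bands,
                        sd0$effects[sd0$effects$target_class == "G2", ],
                        seed = 9)
  pp <- preprocess(ds)
  X <- pp$intensities; lab <- pp$labels
  for (kind in c("pcalda", "plsda")) {
    acc <- vapply(1:6, function(k) {
      if (kind == "pcalda") {
        m <- fit_pca_lda(X, lab, k, "G2"); mean(predict_pca_lda(m, X)$labels == lab)
      } else {
        m <- fit_pls_da(X, lab, k, "G2"); mean(predict_pls_da(m, X)$labels == lab)
      }
    }, numeric(1))
    expect_true(all(diff(acc) >= -1e-9), label = kind)
  }
})

test_that("cross-validated selection follows the one-standard-error rule", {
  set.seed(10)
  # two informative dimensions + noise
  n <- 120
  lab <- rep(c("G1", "G2"), each = n / 2)
  mu <- ifelse(lab == "G2", 1.6, -1.6)
  X <- cbind(mu + rnorm(n), -mu + rnorm(n), matrix(rnorm(n * 8), n))
  folds <- venetian_blinds(n, 10)
  rep <- select_components(X, lab, folds, k_max = 8, model_kind = "plsda",
                           positive_class = "G2")
  expect_lte(rep$n_components_chosen, 4)
  expect_gt(max(rep$cv_accuracy_by_k$mean_accuracy), 0.85)

  # pure noise: all component counts hover at chance
  Xn <- matrix(rnorm(n * 10), n)
  repn <- select_components(Xn, sample(lab), folds, k_max = 5,
                            model_kind = "pcalda", positive_class = "G2")
  expect_true(all(abs(repn$cv_accuracy_by_k$mean_accuracy - 0.5) < 0.2))

  # k_max = 1 returns 1
  rep1 <- select_components(X, lab, folds, k_max = 1, model_kind = "plsda",
                            positive_class = "G2")
  expect_equal(rep1$n_components_chosen, 1)
})

test_that("model input validation catches the contract violations", {
  X <- matrix(rnorm(40), 10)
  expect_error(fit_pca_lda(X, rep("G1", 10), 2), "two classes")
  lab <- rep(c("G1", "G2"), each = 5)
  expect_error(fit_pls_da(X, rep("G1", 10), 2), "two classes")
  m <- fit_pls_da(X, lab, 2, positive_class = "G2",
                  wavenumbers = seq(116, 104, by = -4))
  expect_error(predict_pls_da(m, X[, 1:3]), "axis mismatch")
  expect_error(predict_pls_da(m, X, wavenumbers = seq(104, 116, by = 4)),
               "axis mismatch")
})
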