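test_that("truncation keeps the closed fingerprint interval", {
  sd0 <- default_study_design()
  ds <- generate_cohort(sd0$design, sd0$bands, NULL, seed = 1)
  tr <- truncate_fingerprint(ds, 900, 1800)
  # (1800 - 900) / 4 + 1 points on the 4 cm^-1 grid, both ends included
  expect_equal(length(tr$wavenumbers), 226)
  expect_true(all(tr$wavenumbers >= 900 & tr$wavenumbers <= 1800))
  expect_identical(tr$stage_tag, "truncated")
  # full-range truncation is the identity on the data
  full <- truncate_fingerprint(ds, min(ds$wavenumbers), max(ds$wavenumbers))
  expect_identical(full$intensities, ds$intensities)
  expect_error(truncate_fingerprint(ds, 5000, 6000), "does not intersect")
})

test_that("SG kernel matches the least-squares normal-equations oracle", {
  # brute force: fit a quadratic over offsets -3..3, second derivative = 2 a2
  h <- 3
  A <- outer(-h:h, 0:2, `^`)
  proj <- solve(t(A) %*% A) %*% t(A)       # coefficient extractor
  expected <- 2 * proj[3, ]                # d2/dx2 of a0+a1 x+a2 x^2 at 0
  expect_equal(sg_kernel(7, 2, 2, spacing = 1), expected, tolerance = 1e-12)

  # spacing scaling
  expect_equal(sg_kernel(7, 2, 2, spacing = 4), expected / 16,
               tolerance = 1e-12)

  # smoothing kernel preserves constants; derivative kernels annihilate
  # constants and linear ramps
  k0 <- sg_kernel(9, 3, 0)
  expect_equal(sum(k0), 1, tolerance = 1e-12)
  k2 <- sg_kernel(7, 2, 2)
  expect_equal(sum(k2), 0, tolerance = 1e-12)
  expect_equal(sum(k2 * (-3:3)), 0, tolerance = 1e-12)
  # symmetry for an even derivative order
  expect_equal(k2, rev(k2), tolerance = 1e-12)

  expect_error(sg_kernel(6, 2, 2), "odd")
})

test_that("SG kernel agrees with the signal package's filter design", {
  skip_if_not_installed("signal")
  ours <- sg_kernel(7, 2, 2, spacing = 1)
  # signal::sgolay returns the full filter matrix; its centre row is the
  # interior kernel for the m-th derivative (times m! by their convention)
  theirs <- signal::sgolay(p = 2, n = 7, m = 2)[4, ]
  expect_equal(ours, as.numeric(theirs) * factorial(2) / factorial(2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("second derivative reproduces polynomials exactly, edges included", {
  p <- 31
  wn <- seq(1800, by = -4, length.out = p)
  a <- 0.003; b <- -2; cc <- 5
  quad <- a * wn^2 + b * wn + cc
  ds <- spectral_dataset(wn, rbind(rep(7, p), quad),
                         c("s1", "s2"), c("p1", "p2"), c("G1", "G1"))
  out <- second_derivative(ds)
  expect_identical(out$stage_tag, "derivative")
  # constant row -> all zero
  expect_equal(max(abs(out$intensities[1, ])), 0, tolerance = 1e-12)
  # quadratic row -> constant 2a everywhere (polyorder 2 reproduces it)
  expect_equal(out$intensities[2, ], rep(2 * a, p), tolerance = 1e-9,
               ignore_attr = TRUE)
  # trim mode drops the half-window at each end
  tr <- second_derivative(ds, edges = "trim")
  expect_equal(length(tr$wavenumbers), p - 6)
  expect_error(second_derivative(toy_dataset(p = 5)), "fewer wavenumbers")
})

test_that("interior second derivatives equal sliding quadratic fits", {
  set.seed(42)
  p <- 25
  wn <- seq(1800, by = -4, length.out = p)
  y <- rnorm(p)
  ds <- spectral_dataset(wn, matrix(y, 1), "s1", "p1", "G1")
  out <- second_derivative(ds)$intensities[1, ]
  spacing <- 4
  for (i in 4:(p - 3)) {
    win <- (i - 3):(i + 3)
    fit <- lm(y[win] ~ poly(seq(-3, 3), 2, raw = TRUE))
    expect_equal(out[i], 2 * coef(fit)[[3]] / spacing^2, tolerance = 1e-8)
  }
})

test_that("vector normalisation yields unit rows and flags zero spectra", {
  wn <- c(1000, 996)
  ds <- spectral_dataset(wn, rbind(c(3, 4), c(0.6, 0.8)),
                         c("s1", "s2"), c("p1", "p2"), c("G1", "G1"))
  out <- vector_normalize(ds)
  expect_equal(out$intensities[1, ], c(0.6, 0.8), ignore_attr = TRUE)
  # already-unit row unchanged (idempotence)
  expect_equal(out$intensities[2, ], c(0.6, 0.8), ignore_attr = TRUE)
  expect_identical(out$stage_tag, "normalized")

  set.seed(9)
  big <- toy_dataset(n_patients = 6, replicates = 2, p = 9)
  expect_equal(rowSums(vector_normalize(big)$intensities^2),
               rep(1, 12), tolerance = 1e-12, ignore_attr = TRUE)

  zero <- spectral_dataset(wn, rbind(c(1, 1), c(0, 0)),
                           c("ok", "dead"), c("p1", "p2"), c("G1", "G1"))
  expect_error(vector_normalize(zero), "dead")
})

test_that("the preprocessing chain is invariant to gain and baselines", {
  sd0 <- small_study(class_sizes = c(G1 = 2), replicates = 2)
  ds <- generate_cohort(sd0$design, sd0$bands, NULL, seed = 4)
  base <- preprocess(ds)
  expect_identical(base$stage_tag, "normalized")

  wn <- ds$wavenumbers
  variants <- list(
    gain = ds$intensities * 3.7,                       # positive gain
    const = ds$intensities + 0.25,                     # constant baseline
    linear = sweep(ds$intensities, 2, 0.001 * wn, `+`) # linear baseline
  )
  for (nm in names(variants)) {
    alt <- ds; alt$intensities <- variants[[nm]]
    out <- preprocess(alt)
    expect_equal(out$intensities, base$intensities, tolerance = 1e-10,
                 ignore_attr = TRUE, label = nm)
  }
})
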