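test_that("DBM is antisymmetric, silent on identical classes, and its flag
           count is monotone in the threshold", {
  sd0 <- small_study(class_sizes = c(G1 = 4, G2 = 4), replicates = 3)
  sd0$bands$noise_sd <- 0; sd0$bands$scatter_sd <- 0
  sd0$bands$patient_sd <- 0; sd0$bands$center_jitter_sd <- 0
  sd0$bands$replicate_amp_sd <- 0
  # no effects: classes share one distribution exactly
  ds <- preprocess(generate_cohort(sd0$design, sd0$bands, NULL, seed = 1))
  d0 <- dbm(ds, "G2", "G1")
  expect_equal(max(abs(d0$coefficients)), 0, tolerance = 1e-12)
  expect_equal(nrow(d0$flagged), 0)

  # with an effect, antisymmetry and threshold monotonicity
  eff <- class_effects(1550, "up", 0.3, "G2")
  ds2 <- preprocess(generate_cohort(sd0$design, sd0$bands, eff, seed = 1))
  ab <- dbm(ds2, "G2", "G1"); ba <- dbm(ds2, "G1", "G2")
  expect_equal(ab$coefficients, -ba$coefficients, tolerance = 1e-12)
  flags <- vapply(c(0.001, 0.005, 0.01, 0.05),
                  function(th) nrow(dbm(ds2, "G2", "G1", th)$flagged),
                  numeric(1))
  expect_true(all(diff(flags) <= 0))
  expect_error(dbm(ds, "G2", "G1R"), "absent")
})

test_that("top_peaks finds isolated spikes, handles plateaus and monotone
           input, and is not invariant to constant shifts", {
  wn <- seq(1800, by = -4, length.out = 50)
  coefs <- rep(0, 50)
  spikes <- c(5, 11, 17, 23, 29, 35, 41, 47)
  coefs[spikes] <- c(0.9, -0.8, 0.7, -0.6, 0.5, -0.4, 0.3, -0.2)
  pk <- top_peaks(coefs, wn, 8)
  expect_equal(pk$wavenumber, wn[spikes])          # sorted by magnitude
  expect_equal(pk$coefficient, coefs[spikes])

  # plateau counts once, at its leftmost point
  plat <- c(0, 1, 1, 1, 0, 2, 0)
  pp <- top_peaks(plat, seq(1800, by = -4, length.out = 7), 2)
  expect_equal(pp$coefficient, c(2, 1))
  expect_equal(pp$wavenumber[2], 1796)             # leftmost of the plateau

  # monotone input: warning and endpoint fallback
  expect_warning(
    expect_warning(mono <- top_peaks(1:10, seq(1836, 1800, by = -4), 2),
                   "no interior extrema"),
    "only 1 peak")
  expect_equal(nrow(mono), 1)

  # |.| extrema move under a constant shift: signed coefficients are the
  # physical quantity, the magnitudes are not shift-invariant
  v <- c(0.2, -0.5, 0.2, 0.4, 0.2)
  wn5 <- seq(1816, 1800, by = -4)
  p_raw <- top_peaks(v, wn5, 1)
  p_shift <- top_peaks(v + 0.5, wn5, 1)
  expect_false(p_raw$wavenumber == p_shift$wavenumber)

  expect_error(top_peaks(c(1, 2), c(1800, 1796), 1), "at least 3")
})

test_that("marker ANOVA matches the pooled t-test and the degenerate cases", {
  wn <- seq(1808, 1800, by = -4)
  vals <- c(4.1, 3.9, 4.4, 5.2, 5.6, 5.0, 4.9, 5.3)
  X <- cbind(vals, matrix(1, 8, 2))
  ds <- spectral_dataset(wn, X, sprintf("s%d", 1:8), sprintf("p%d", 1:8),
                         rep(c("G1", "G2"), each = 4))
  p_anova <- marker_anova(ds, 1808)
  p_t <- t.test(vals[1:4], vals[5:8], var.equal = TRUE)$p.value
  expect_equal(p_anova, p_t, tolerance = 1e-12)     # F = t^2 equivalence

  # identical groups: no evidence, p = 1
  ds_same <- ds; ds_same$intensities[, 1] <- rep(c(1, 2, 3, 4), 2)
  expect_equal(marker_anova(ds_same, 1808), 1)

  # off-axis wavenumber beyond half a spacing
  expect_error(marker_anova(ds, 1790), "off-axis")
  # patient-level mode collapses replicates first
  expect_silent(marker_anova(ds, 1808, level = "patient"))
})

test_that("a strong injected effect is overwhelmingly significant at its
           wavenumber", {
  sd0 <- small_study(class_sizes = c(G1 = 10, G2 = 8), replicates = 5)
  eff <- class_effects(1454, "up", 0.3, "G2")
  pp <- preprocess(generate_cohort(sd0$design, sd0$bands, eff, seed = 17))
  expect_lt(marker_anova(pp, 1454), 1e-3)
})

test_that("direction calls follow the injected trend and flip with class
           order", {
  sd0 <- small_study(class_sizes = c(G1 = 6, G2 = 6), replicates = 4)
  eff <- class_effects(1550, "up", 0.3, "G2")
  ds <- generate_cohort(sd0$design, sd0$bands, eff, seed = 19)   # raw scale
  expect_equal(intensity_direction(ds, 1550, "G2", "G1"), "up")
  expect_equal(intensity_direction(ds, 1550, "G1", "G2"), "down")

  # exact tie exercises the warning path
  wn <- seq(1808, 1800, by = -4)
  tie <- spectral_dataset(wn, matrix(1, 4, 3), sprintf("s%d", 1:4),
                          sprintf("p%d", 1:4), rep(c("G1", "G2"), 2))
  expect_warning(d <- intensity_direction(tie, 1804, "G1", "G2"), "tie")
  expect_equal(d, "down")
})

test_that("marker tables are sorted, tagged consistently and recover
           injected markers under favourable settings", {
  ds <- recovery_cohort(seed = 23, class_sizes = c(G1 = 12, G2 = 8))
  pp <- preprocess(ds)
  m <- fit_pls_da(pp$intensities, pp$labels, 2, "G2",
                  wavenumbers = pp$wavenumbers)
  mk <- build_marker_table(m, pp, n_peaks = 8)
  expect_s3_class(mk, "marker_table")
  expect_lte(nrow(mk), 8)
  expect_true(all(diff(abs(mk$coefficient)) <= 1e-12))
  expect_true(all(mk$p_value >= 0 & mk$p_value <= 1))
  want <- ifelse(mk$p_value < 0.001, "**", ifelse(mk$p_value < 0.05, "*", ""))
  expect_identical(mk$significance, want)

  injected <- recovery_effects()$wavenumber
  hit <- vapply(injected, function(w) any(abs(mk$wavenumber - w) <= 4),
                logical(1))
  expect_gte(mean(hit), 5 / 6)

  # DBM route produces the same table structure
  mk2 <- build_marker_table(dbm(pp, "G2", "G1"), pp, n_peaks = 6)
  expect_s3_class(mk2, "marker_table")
  expect_lte(nrow(mk2), 6)
  # optional FDR column
  mk3 <- build_marker_table(m, pp, n_peaks = 4, fdr = TRUE)
  expect_true("p_adjusted" %in% names(mk3))
})
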