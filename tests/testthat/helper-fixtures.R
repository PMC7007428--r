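# Small in-code fixtures shared across the suite.

# minimal hand-built dataset: n patients x r replicates on a short axis
toy_dataset <- function(n_patients = 3, replicates = 1, p = 5,
                        labels = NULL, seed = 1, stage_tag = "raw") {
  set.seed(seed)
  wn <- seq(2000, by = -4, length.out = p)
  n <- n_patients * replicates
  if (is.null(labels)) labels <- rep("G1", n_patients)
  spectral_dataset(
    wavenumbers = wn,
    intensities = matrix(rnorm(n * p, mean = 1), nrow = n),
    spectrum_ids = sprintf("S%03d", seq_len(n)),
    patient_ids = rep(sprintf("P%02d", seq_len(n_patients)),
                      each = replicates),
    labels = rep(labels, each = replicates),
    stage_tag = stage_tag
  )
}

# compact synthetic study: fewer patients and a short axis for fast tests
small_study <- function(class_sizes = c(G1 = 6, G2 = 4, G1R = 3),
                        replicates = 3, effect_magnitude = 0.15) {
  sd0 <- default_study_design(effect_magnitude = effect_magnitude)
  sd0$design <- cohort_design(class_sizes = class_sizes,
                              replicates_per_patient = replicates)
  sd0
}

# the marker set used by recovery experiments: one marker per distinct
# narrow band, magnitudes equalised for second-derivative visibility
recovery_effects <- function() {
  class_effects(
    wavenumber   = c(1750, 1650, 1550, 1470, 1080, 1030),
    direction    = c("down", "up", "down", "up", "down", "up"),
    magnitude    = c(0.36, 0.15, 0.17, 0.26, 0.26, 0.22),
    target_class = "G2")
}

# cohort conditions for the marker-recovery experiment: default noise and
# scatter, symmetric (matched) patient heterogeneity across classes
recovery_cohort <- function(seed, class_sizes = c(G1 = 70, G2 = 24)) {
  sd0 <- default_study_design()
  sd0$bands$center_jitter_sd <- 2
  sd0$design$class_sizes <- class_sizes
  generate_cohort(sd0$design, sd0$bands, recovery_effects(), seed = seed)
}

# independent brute-force greedy maximin selection (Kennard-Stone oracle)
ks_oracle <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  D <- as.matrix(dist(points))
  pairs <- which(D == max(D), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  sel <- as.integer(pairs[1, ])
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    md <- vapply(cand, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, cand[which(md == max(md))[1]])
  }
  sel
}

# brute-force pairwise Mann-Whitney AUC oracle (1/2 credit for ties)
auc_oracle <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}
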