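test_that("simulated traces put the fundamental at speed over period", {
  surf <- surface_spec("S1", spatial_period_mm = 1, amplitude_um = 10,
                       noise_um_rms = 0.01)
  tr <- simulate_trace(surf, speed_mm_s = 10, fs = 2000, duration_s = 4,
                       seed = 3)
  expect_equal(attr(tr, "f0_hz"), 10)
  sp <- compute_spectrum(tr, n_fft = 8192L)
  peak <- sp$frequency[which.max(sp$amplitude)]
  expect_lt(abs(peak - 10), 2000 / 8192 + 1e-9)
  # harmonic at 2 f0 present with the configured roll-off
  a1 <- max(sp$amplitude[abs(sp$frequency - 10) < 1])
  a2 <- max(sp$amplitude[abs(sp$frequency - 20) < 1])
  expect_equal(a2 / a1, surf$harmonic_rolloff, tolerance = 0.05)
})

test_that("aliasing and degenerate surfaces are handled", {
  surf <- surface_spec("S1", 0.1, 5, n_harmonics = 10)
  expect_error(simulate_trace(surf, speed_mm_s = 100, fs = 10000), "aliasing")
  silent <- surface_spec("S0", 1, 0, noise_um_rms = 0)
  tr <- simulate_trace(silent, seed = 1, duration_s = 1)
  expect_true(all(tr$values == 0))
  sp <- spectrum_to_db(compute_spectrum(tr, 8192L))
  D <- subarea_features(sp, default_threshold_model())
  expect_true(all(D == 0))
})

test_that("generators are reproducible under a seed and record it", {
  surf <- surface_spec("S1", 1, 10)
  t1 <- simulate_trace(surf, seed = 7, duration_s = 0.5)
  t2 <- simulate_trace(surf, seed = 7, duration_s = 0.5)
  t3 <- simulate_trace(surf, seed = 8, duration_s = 0.5)
  expect_identical(t1$values, t2$values)
  expect_false(identical(t1$values, t3$values))
  expect_equal(attr(t1, "seed"), 7L)
  fr1 <- simulate_friction(c("a", "b"), seed = 5)
  fr2 <- simulate_friction(c("a", "b"), seed = 5)
  expect_identical(fr1$mu_prime, fr2$mu_prime)
  expect_true(all(fr1$mu_prime > 0.2 & fr1$mu_prime < 1.2))
  p1 <- simulate_panel(panel_spec(), cbind(F1 = rep(0, 3), F2 = rep(0, 3)),
                       seed = 9)
  p2 <- simulate_panel(panel_spec(), cbind(F1 = rep(0, 3), F2 = rep(0, 3)),
                       seed = 9)
  expect_identical(p1$scores, p2$scores)
  expect_equal(attr(p1, "seed"), 9L)
})

test_that("the random-state of the session is not disturbed by generators", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(simulate_trace(surface_spec("S1", 1, 5), seed = 99,
                           duration_s = 0.2))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a noise-free rank-2 panel yields exactly two retained PCs", {
  set.seed(71)
  F <- matrix(rnorm(16, 0, 1.8), 8, 2,
              dimnames = list(sprintf("S%d", 1:8), c("F1", "F2")))
  spec <- panel_spec(n_subjects = 20, cluster_sizes = 20L, noise_sd = 0)
  pan <- simulate_panel(spec, F, seed = 73)
  p <- run_pca(pan)
  expect_length(p$retained, 2L)
})

test_that("an all-zero loading panel is clipped noise with null spectrum", {
  words <- default_words()
  L0 <- matrix(0, 10, 2, dimnames = list(words, c("F1", "F2")))
  spec <- panel_spec(loadings = list(L0, L0), noise_sd = 1)
  F <- matrix(rnorm(16), 8, 2, dimnames = list(sprintf("S%d", 1:8), NULL))
  pan <- simulate_panel(spec, F, seed = 79)
  expect_true(all(abs(pan$scores$score - 4) <= 3))
  X <- vibrotact:::panel_observation_matrix(pan)
  ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  # below the Marchenko-Pastur bulk edge for p/n with slack
  mp_edge <- (1 + sqrt(ncol(X) / nrow(X)))^2
  expect_lt(max(ev), 1.15 * mp_edge)
})

test_that("two sign-flipped clusters are recovered from the default panel", {
  set.seed(83)
  F <- matrix(rnorm(16, 0, 1.6), 8, 2,
              dimnames = list(sprintf("S%d", 1:8), NULL))
  pan <- simulate_panel(panel_spec(), F, seed = 85)
  truth <- attr(pan, "cluster_membership")
  cl <- cluster_subjects(pan, k = 2)
  expect_gte(cluster_agreement(unname(cl$assignments[names(truth)]),
                               unname(truth)), 0.95)
})

test_that("feature tables span the requested dynamic range", {
  ft <- simulate_feature_table(seed = 89, decades = 2)
  expect_equal(nrow(ft), 8L)
  for (cl in grep("^D_", names(ft), value = TRUE)) {
    spread <- log10(max(ft[[cl]]) / min(ft[[cl]]))
    expect_gt(spread, 1.5)
    expect_true(all(ft[[cl]] > 0))
  }
  expect_identical(ft, simulate_feature_table(seed = 89, decades = 2))
})

test_that("a small end-to-end study has coherent shapes and provenance", {
  surfaces <- default_surfaces(4L)
  study <- simulate_study(seed = 5, surfaces = surfaces, n_reps = 2L,
                          panel = panel_spec(n_subjects = 8L,
                                             cluster_sizes = c(4L, 4L)),
                          n_fft = 8192L, duration_s = 0.5)
  expect_length(study$traces, 8L)
  expect_equal(nrow(study$features), 8L)
  expect_setequal(unique(study$features$sample_id),
                  vapply(surfaces, `[[`, character(1), "sample_id"))
  expect_equal(sort(vibrotact:::feature_columns(study$legacy_features)),
               sort(paste0("A_", RECEPTORS)))
  expect_equal(rownames(study$factor_scores), sort(study$metadata$sample_id))
  expect_length(study$panel$subjects, 8L)
  # subarea and legacy tables partition the same total area per spectrum
  dsum <- rowSums(study$features[grep("^D_", names(study$features))])
  asum <- rowSums(study$legacy_features[grep("^A_",
                                             names(study$legacy_features))])
  expect_equal(dsum, asum, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("planted-model recovery is exact at zero noise", {
  rec <- end_to_end_recovery(seed = 91, sigma = 0)
  expect_true(rec$planted_won)
  expect_lt(max(rec$coef_rel_error), 1e-8)
})

test_that("a planted linear law over two decades is selected as linear", {
  rec <- end_to_end_recovery(seed = 93, family = "linear",
                             beta = c(1, 0.05), sigma = 0.01)
  expect_equal(rec$selected_family, "linear")
  expect_lt(max(rec$coef_rel_error), 0.05)
})
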