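# Synthetic generators: textured-surface tracing vibrations (fundamental at
# tracing-speed / spatial-period with harmonics and broadband noise),
# friction coefficients, and semantic-differential panels with planted
# cluster / factor structure. Every generator is deterministic under a seed
# and records the seed in its output.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Describe a textured surface
#'
#' Spectral phenomenology of a periodically textured plate: tracing at
#' speed v excites a fundamental at `v / spatial_period` plus harmonics
#' with geometric roll-off, on top of broadband (stick-slip and sensor)
#' noise. No contact-mechanics model is implied.
#'
#' @param sample_id Sample identifier.
#' @param spatial_period_mm Texture period (mm), > 0.
#' @param amplitude_um Fundamental displacement amplitude (um peak), >= 0.
#' @param n_harmonics Number of harmonics (including the fundamental).
#' @param harmonic_rolloff Amplitude ratio between consecutive harmonics,
#'   in (0, 1\].
#' @param noise_um_rms Broadband Gaussian noise level (um RMS).
#' @return Object of class `surface_spec`.
#' @export
surface_spec <- function(sample_id, spatial_period_mm, amplitude_um,
                         n_harmonics = 5L, harmonic_rolloff = 0.5,
                         noise_um_rms = 0.05) {
  stopifnot(spatial_period_mm > 0, amplitude_um >= 0, n_harmonics >= 1L,
            harmonic_rolloff > 0, harmonic_rolloff <= 1, noise_um_rms >= 0)
  structure(list(sample_id = as.character(sample_id),
                 spatial_period_mm = spatial_period_mm,
                 amplitude_um = amplitude_um,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_rolloff = harmonic_rolloff,
                 noise_um_rms = noise_um_rms),
            class = "surface_spec")
}

#' Default set of eight synthetic plates
#'
#' Eight surfaces emulating the shape of the study's sample set: spatial
#' periods between 0.4 and 2 mm and fundamental amplitudes log-spaced over
#' roughly two decades, so downstream features span a realistic range.
#'
#' @param n_samples Number of plates (default 8).
#' @return List of [surface_spec()] objects named `S1`..`Sn`.
#' @export
default_surfaces <- function(n_samples = 8L) {
  stopifnot(n_samples >= 1L)
  periods <- rep_len(c(0.5, 1, 2, 0.8, 1.5, 0.4, 1.2, 0.6), n_samples)
  amps <- 10^seq(log10(0.5), log10(40), length.out = n_samples)
  lapply(seq_len(n_samples), function(i) {
    surface_spec(sprintf("S%d", i), periods[i], amps[i])
  })
}

#' Simulate a tracing-vibration displacement trace
#'
#' Sum of `n_harmonics` sinusoids of the fundamental
#' `f0 = speed / spatial_period` (random phases) plus white Gaussian noise.
#' Defaults mirror the study's recording conditions: 10 mm/s tracing speed,
#' 30 mm distance (3 s) and a 10 kHz sampling rate.
#'
#' @param surface A [surface_spec()].
#' @param speed_mm_s Tracing speed (mm/s).
#' @param fs Sampling rate (Hz); must exceed twice the highest harmonic.
#' @param duration_s Trace duration (s).
#' @param seed Integer seed; the trace is reproducible given the seed,
#'   which is stored in the result's `seed` attribute.
#' @param repetition Repetition index recorded on the trace.
#' @return A [vibration_trace()] in micrometres.
#' @examples
#' tr <- simulate_trace(surface_spec("S1", 1, 10), seed = 1)
#' # fundamental at 10 mm/s / 1 mm = 10 Hz
#' @export
simulate_trace <- function(surface, speed_mm_s = 10, fs = 10000,
                           duration_s = 3, seed = 1L, repetition = 1L) {
  stopifnot(inherits(surface, "surface_spec"), speed_mm_s > 0, fs > 0,
            duration_s > 0)
  f0 <- speed_mm_s / surface$spatial_period_mm
  if (fs < 2 * f0 * surface$n_harmonics) {
    stop(sprintf("aliasing: fs = %g Hz < 2 x highest harmonic %g Hz",
                 fs, f0 * surface$n_harmonics))
  }
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1L) / fs
  x <- with_seed(seed, {
    phases <- stats::runif(surface$n_harmonics, 0, 2 * pi)
    sig <- numeric(n)
    for (h in seq_len(surface$n_harmonics)) {
      a <- surface$amplitude_um * surface$harmonic_rolloff^(h - 1L)
      sig <- sig + a * sin(2 * pi * h * f0 * t + phases[h])
    }
    sig + if (surface$noise_um_rms > 0) {
      stats::rnorm(n, 0, surface$noise_um_rms)
    } else 0
  })
  tr <- vibration_trace(x, fs, "micrometer", surface$sample_id, repetition)
  attr(tr, "seed") <- as.integer(seed)
  attr(tr, "f0_hz") <- f0
  tr
}

#' Simulate per-sample dynamic friction coefficients
#'
#' Draws mu' uniformly over `range` (default \[0.2, 1.2\], plausible for
#' plastics slid under light normal force).
#'
#' @param sample_ids Character vector of sample ids.
#' @param range Lower/upper bounds for mu'.
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `mu_prime` with a `seed` attribute.
#' @export
simulate_friction <- function(sample_ids, range = c(0.2, 1.2), seed = 1L) {
  stopifnot(length(sample_ids) >= 1L, range[1L] > 0, range[1L] < range[2L])
  mu <- with_seed(seed, stats::runif(length(sample_ids), range[1L], range[2L]))
  structure(data.frame(sample_id = as.character(sample_ids), mu_prime = mu,
                       stringsAsFactors = FALSE),
            seed = as.integer(seed))
}

#' Default semantic-differential word list
#'
#' Ten tactile adjectives of the kind used on seven-step unipolar scales.
#'
#' @return Character vector of 10 words.
#' @export
default_words <- function() {
  c("smooth", "sticky", "pasty", "friction_drag", "moist",
    "sleek", "slippery", "velvety", "fine", "rough")
}

#' Default planted word-factor loadings
#'
#' Two latent tactile factors: the first five words load on factor 1, the
#' last five on factor 2 (loading 0.9, within \[-1, 1\]).
#'
#' @param words Word list.
#' @return `length(words)` x 2 loading matrix.
#' @export
default_panel_loadings <- function(words = default_words()) {
  n <- length(words)
  half <- ceiling(n / 2)
  L <- matrix(0, n, 2L, dimnames = list(words, c("F1", "F2")))
  L[seq_len(half), 1L] <- 0.9
  L[(half + 1L):n, 2L] <- 0.9
  L
}

#' Describe a synthetic sensory panel
#'
#' @param n_subjects Number of subjects (default 35, split 10/25 across two
#'   clusters as in the study).
#' @param cluster_sizes Integer sizes summing to `n_subjects`.
#' @param words Word list.
#' @param loadings List of word x factor loading matrices, one per
#'   cluster; entries must lie in \[-1, 1\]. Default: the planted
#'   two-factor structure for cluster 1 and its sign-flipped mirror for
#'   cluster 2 (opposite response polarity).
#' @param noise_sd Subject noise SD on the 1-7 scale (default 1, about one
#'   scale step).
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(n_subjects = 35L, cluster_sizes = c(10L, 25L),
                       words = default_words(), loadings = NULL,
                       noise_sd = 1) {
  stopifnot(sum(cluster_sizes) == n_subjects, all(cluster_sizes >= 1L),
            noise_sd >= 0)
  if (is.null(loadings)) {
    L <- default_panel_loadings(words)
    loadings <- rep(list(L), length(cluster_sizes))
    if (length(loadings) > 1L) {
      for (j in seq(2L, length(loadings), by = 2L)) {
        loadings[[j]] <- -loadings[[j]]
      }
    }
  }
  stopifnot(length(loadings) == length(cluster_sizes))
  for (L in loadings) {
    stopifnot(is.matrix(L), nrow(L) == length(words), max(abs(L)) <= 1)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 cluster_sizes = as.integer(cluster_sizes),
                 words = words, loadings = loadings, noise_sd = noise_sd),
            class = "panel_spec")
}

#' Simulate a semantic-differential sensory panel
#'
#' Each subject belongs to a cluster; their score for (sample, word) is
#' `4 + loading[word, ] . factor_scores[sample, ] + noise`, rounded and
#' clipped to the 1..7 scale. Subjects are named `subj01`.. with cluster 1
#' first, so the planted membership is `rep(seq, cluster_sizes)`.
#'
#' @param spec A [panel_spec()].
#' @param sample_factor_scores Samples x factors numeric matrix (row names
#'   = sample ids) giving each sample's position on the latent tactile
#'   factors; typically derived from feature ground truth.
#' @param seed Integer seed.
#' @return A [sensory_panel()] with attributes `seed` and
#'   `cluster_membership`.
#' @export
simulate_panel <- function(spec, sample_factor_scores, seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"), is.matrix(sample_factor_scores),
            nrow(sample_factor_scores) >= 1L,
            ncol(sample_factor_scores) == ncol(spec$loadings[[1L]]))
  samples <- rownames(sample_factor_scores)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(sample_factor_scores)))
  membership <- rep(seq_along(spec$cluster_sizes), spec$cluster_sizes)
  subjects <- sprintf("subj%02d", seq_len(spec$n_subjects))
  rows <- with_seed(seed, {
    out <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      L <- spec$loadings[[membership[s]]]
      mu <- 4 + sample_factor_scores %*% t(L)  # samples x words
      eps <- matrix(stats::rnorm(length(mu), 0, spec$noise_sd), nrow(mu))
      sc <- round(mu + eps)
      sc[sc < 1] <- 1
      sc[sc > 7] <- 7
      out[[s]] <- data.frame(
        subject = subjects[s],
        sample = rep(samples, times = ncol(sc)),
        word = rep(spec$words, each = nrow(sc)),
        score = as.vector(sc), stringsAsFactors = FALSE)
    }
    out
  })
  panel <- sensory_panel(do.call(rbind, rows))
  attr(panel, "seed") <- as.integer(seed)
  attr(panel, "cluster_membership") <- stats::setNames(membership, subjects)
  panel
}

#' Simulate a per-sample feature table with planted spread
#'
#' Generates repetition-mean subarea features whose values span
#' `decades` orders of magnitude across samples (log-uniform with jitter),
#' plus friction coefficients — the shape the regression stage consumes.
#' Used to plant known regression laws without running the full signal
#' pipeline.
#'
#' @param n_samples Number of samples (default 8).
#' @param seed Integer seed.
#' @param decades Log10 range of each feature across samples.
#' @param labels Feature labels (default: the eight canonical firing
#'   combinations of the packaged model).
#' @return Data frame `sample_id`, `D_<label>` columns, `mu_prime`, with a
#'   `seed` attribute.
#' @export
simulate_feature_table <- function(n_samples = 8L, seed = 1L, decades = 2,
                                   labels = NULL) {
  if (is.null(labels)) labels <- enumerate_combinations(default_threshold_model())
  stopifnot(n_samples >= 3L, decades > 0)
  with_seed(seed, {
    ids <- sprintf("S%d", seq_len(n_samples))
    base <- seq(0, decades, length.out = n_samples)
    out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (lab in labels) {
      u <- sample(base) + stats::runif(n_samples, -0.05, 0.05)
      out[[paste0("D_", lab)]] <- 10^u * stats::runif(1L, 2, 8)
    }
    out$mu_prime <- stats::runif(n_samples, 0.2, 1.2)
    structure(out, seed = as.integer(seed))
  })
}

#' Simulate a complete tactile-estimation study
#'
#' Generates the full fixture set under one seed: `n_reps` vibration traces
#' per surface, friction metadata, Hamming-windowed spectra, subarea and
#' legacy feature tables, latent sample factor scores derived from the
#' feature ground truth (standardised log10 total area and friction), and a
#' sensory panel driven by those factors. Defaults mirror the study shape:
#' 8 samples, 11 repetitions, 3 s at 10 kHz, 35 subjects split 10/25.
#'
#' @param seed Integer master seed (per-trace seeds are derived from it).
#' @param surfaces List of [surface_spec()]s.
#' @param n_reps Repetitions per surface.
#' @param panel A [panel_spec()].
#' @param model Threshold model for feature extraction.
#' @param n_fft FFT length.
#' @param speed_mm_s,fs,duration_s Tracing conditions.
#' @return List with elements `traces`, `metadata`, `spectra`, `features`
#'   (subarea), `legacy_features`, `factor_scores`, `panel`, `seed`.
#' @export
simulate_study <- function(seed = 1L, surfaces = default_surfaces(),
                           n_reps = 11L, panel = panel_spec(),
                           model = default_threshold_model(),
                           n_fft = 32768L, speed_mm_s = 10, fs = 10000,
                           duration_s = 3) {
  ids <- vapply(surfaces, `[[`, character(1L), "sample_id")
  traces <- list()
  for (i in seq_along(surfaces)) {
    for (r in seq_len(n_reps)) {
      traces[[length(traces) + 1L]] <-
        simulate_trace(surfaces[[i]], speed_mm_s, fs, duration_s,
                       seed = seed * 1000L + i * 100L + r, repetition = r)
    }
  }
  metadata <- simulate_friction(ids, seed = seed)
  spectra <- lapply(traces, compute_spectrum, n_fft = n_fft)
  feats <- extract_features(spectra, model, metadata, method = "subarea")
  legacy <- extract_features(spectra, model, metadata, method = "legacy")
  per_sample <- stats::aggregate(feats[feature_columns(feats)],
                                 by = list(sample_id = feats$sample_id),
                                 FUN = mean)
  zs <- function(x) as.numeric(scale(x))
  F <- cbind(F1 = zs(log10(rowSums(per_sample[-1L]) + 1e-6)),
             F2 = zs(metadata$mu_prime[match(per_sample$sample_id,
                                             metadata$sample_id)]))
  rownames(F) <- per_sample$sample_id
  list(traces = traces, metadata = metadata, spectra = spectra,
       features = feats, legacy_features = legacy, factor_scores = F,
       panel = simulate_panel(panel, F, seed = seed + 1L),
       seed = as.integer(seed))
}

#' Planted-model recovery report
#'
#' Plants a known regression law on one feature of a synthetic feature
#' table, runs leave-one-sample-out selection over all four families, and
#' reports whether the planted family won and how well its coefficients
#' were recovered.
#'
#' @param seed Integer seed (drives the feature table and the noise).
#' @param family Planted family: `"linear"` or `"logarithmic"`.
#' @param feature Feature column the law acts on.
#' @param beta `c(beta0, beta1)` of the planted law (`y = beta0 + beta1 x`
#'   or `y = beta0 + beta1 log10(x)`).
#' @param sigma Gaussian noise SD added to y.
#' @param n_samples Number of samples.
#' @return List: `selected_family`, `planted_won`, `coefficients` (refit of
#'   the planted spec on all samples), `coef_rel_error`, `selection`.
#' @export
end_to_end_recovery <- function(seed = 1L, family = c("logarithmic", "linear"),
                                feature = "D_ALL", beta = c(2, 1.5),
                                sigma = 0.01, n_samples = 8L) {
  family <- match.arg(family)
  ft <- simulate_feature_table(n_samples = n_samples, seed = seed)
  x <- ft[[feature]]
  yhat <- if (family == "logarithmic") beta[1L] + beta[2L] * log10(x)
          else beta[1L] + beta[2L] * x
  y <- yhat + with_seed(seed + 1L, stats::rnorm(n_samples, 0, sigma))
  targets <- data.frame(sample_id = ft$sample_id, y = y)
  sel <- select_models(list(B = ft), targets,
                       candidates = list(B = c(feature, "mu_prime")))
  fit <- fit_model(model_spec(family, feature), ft, y)
  rel <- abs(fit$coefficients[1:2] - beta) / abs(beta)
  list(selected_family = sel$best$family,
       planted_won = identical(sel$best$family, family),
       coefficients = fit$coefficients,
       coef_rel_error = unname(rel),
       selection = sel, seed = as.integer(seed))
}
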