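# Firing-combination subarea features: areas (dB x decades) of the region
# between a dB amplitude spectrum and the lowest receptor threshold,
# partitioned by the amplitude band structure of the threshold model.

as_db_spectrum <- function(spec, ref = 1, floor_db = -120) {
  if (inherits(spec, "db_spectrum")) return(spec)
  if (inherits(spec, "amplitude_spectrum")) {
    return(spectrum_to_db(spec, ref = ref, floor_db = floor_db))
  }
  stop("'spec' must be an amplitude_spectrum or db_spectrum")
}

# per-bin integration cells over f_range: centers, widths in decades
spectrum_cells <- function(frequency, f_range) {
  stopifnot(length(f_range) == 2L, f_range[1L] > 0, f_range[1L] < f_range[2L])
  f <- frequency
  n <- length(f)
  mid <- (f[-1L] + f[-n]) / 2
  edges_lo <- c(f[1L] - (mid[1L] - f[1L]), mid)
  edges_hi <- c(mid, f[n] + (f[n] - mid[n - 1L]))
  if (min(edges_lo) > f_range[1L] + 1e-9 || max(edges_hi) < f_range[2L] - 1e-9) {
    stop(sprintf("spectrum does not cover [%g, %g] Hz: bins span [%g, %g] Hz",
                 f_range[1L], f_range[2L], min(edges_lo), max(edges_hi)))
  }
  lo <- pmin(pmax(edges_lo, f_range[1L]), f_range[2L])
  hi <- pmin(pmax(edges_hi, f_range[1L]), f_range[2L])
  keep <- which(hi > lo & f > 0)
  list(index = keep, f = f[keep], width = log10(hi[keep]) - log10(lo[keep]))
}

#' Firing-combination subarea features of a spectrum
#'
#' Integrates, in (log10 frequency) x dB coordinates, the region between the
#' dB amplitude spectrum and the lowest defined receptor threshold over
#' `f_range`. For each spectrum bin the vertical column from the lowest
#' threshold up to the spectrum level is cut by [band_structure()] into
#' slabs; each slab's height times the bin's width in decades accrues to the
#' slab's firing combination. Bins at or below the lowest threshold
#' contribute nothing, so every feature can be zero. By construction the
#' features sum exactly to the total area between spectrum and lowest
#' threshold.
#'
#' @param spec An `amplitude_spectrum` or `db_spectrum` covering `f_range`.
#' @param model A [threshold_model()].
#' @param f_range Integration range in Hz (default \[0.5, 800\], the span of
#'   the threshold curves).
#' @param labels Combination labels to report; defaults to
#'   [enumerate_combinations()] of the model (the eight canonical labels for
#'   the packaged model). Labels encountered during integration are always
#'   included.
#' @return Named numeric vector of areas (dB x decades), with attributes
#'   `sample_id` and `repetition` carried from the spectrum.
#' @examples
#' m <- default_threshold_model()
#' f <- seq(0.25, 800.25, by = 0.5)
#' quiet <- db_spectrum(f, rep(-120, length(f)))
#' subarea_features(quiet, m)   # all zero
#' @export
subarea_features <- function(spec, model, f_range = c(0.5, 800),
                             labels = NULL) {
  spec <- as_db_spectrum(spec)
  if (is.null(labels)) labels <- enumerate_combinations(model)
  cells <- spectrum_cells(spec$frequency, f_range)
  D <- stats::setNames(numeric(length(labels)), labels)
  s <- spec$db[cells$index]
  thr <- threshold_matrix(model, cells$f)
  recs <- colnames(thr)
  canon <- match(recs, RECEPTORS)
  label_cache <- new.env(parent = emptyenv())
  for (i in seq_along(cells$f)) {
    ti <- thr[i, ]
    def <- which(!is.na(ti))
    if (length(def) == 0L || s[i] <= min(ti[def])) next
    ord <- def[threshold_order(ti[def], canon[def])]
    t_sorted <- cummax(ti[ord])
    # slab labels for this receptor ordering (cached across bins)
    key <- paste(ord, collapse = ".")
    labs <- label_cache[[key]]
    if (is.null(labs)) {
      labs <- vapply(seq_along(ord), function(k) {
        combo_label(recs[ord[seq_len(k)]])
      }, character(1L))
      label_cache[[key]] <- labs
    }
    upper <- c(t_sorted[-1L], Inf)
    h <- pmax(0, pmin(s[i], upper) - t_sorted)
    for (k in which(h > 0)) {
      lab <- labs[k]
      if (is.na(match(lab, names(D)))) D[lab] <- 0
      D[lab] <- D[lab] + h[k] * cells$width[i]
    }
  }
  structure(D, sample_id = spec$sample_id, repetition = spec$repetition)
}

#' Lowest-threshold-band features (prior-study baseline)
#'
#' Baseline feature extraction that ignores simultaneous firing: the
#' frequency axis is partitioned by which receptor holds the lowest
#' threshold at each bin, and within each band the whole area between the
#' spectrum and that lowest threshold is accumulated. Bands led by the same
#' receptor are pooled, giving one pooled area per receptor (zero where a
#' receptor is never the lowest; under the packaged model only the SA I and
#' FA II bands are non-degenerate). The exact construction of the original
#' baseline is not published in full, so this is a reconstruction and is
#' labelled as such in outputs.
#'
#' @inheritParams subarea_features
#' @return Named numeric vector `A_SAI`, `A_SAII`, `A_FAI`, `A_FAII`
#'   (dB x decades) with provenance attributes. The sum over receptors
#'   equals the sum of [subarea_features()]: both partition the same
#'   region.
#' @export
legacy_features <- function(spec, model, f_range = c(0.5, 800)) {
  spec <- as_db_spectrum(spec)
  cells <- spectrum_cells(spec$frequency, f_range)
  recs <- intersect(RECEPTORS, names(model$segments))
  A <- stats::setNames(numeric(length(RECEPTORS)), paste0("A_", RECEPTORS))
  thr <- threshold_matrix(model, cells$f)
  s <- spec$db[cells$index]
  for (i in seq_along(cells$f)) {
    ti <- thr[i, ]
    if (all(is.na(ti))) next
    low <- which.min(ti)  # ties: first in canonical order
    h <- s[i] - ti[low]
    if (h > 0) {
      key <- paste0("A_", recs[low])
      A[key] <- A[key] + h * cells$width[i]
    }
  }
  structure(A, sample_id = spec$sample_id, repetition = spec$repetition,
            method = "A-method (reconstructed)")
}

#' Build a feature table from spectra
#'
#' Applies [subarea_features()] (method `"subarea"`, the proposed B method)
#' or [legacy_features()] (method `"legacy"`, the reconstructed A baseline)
#' to a list of spectra and joins per-sample metadata.
#'
#' @param spectra List of `amplitude_spectrum` / `db_spectrum` objects with
#'   distinct (sample_id, repetition) pairs.
#' @param model A [threshold_model()].
#' @param metadata Optional data frame with `sample_id` and `mu_prime`
#'   columns (see [read_sample_metadata()]); merged onto the rows.
#' @param method Feature method.
#' @param f_range Integration range (Hz).
#' @return Data frame: `sample_id`, `repetition`, one `D_<combo>` (or
#'   `A_<receptor>`) column per feature, and `mu_prime` when metadata is
#'   supplied.
#' @export
extract_features <- function(spectra, model, metadata = NULL,
                             method = c("subarea", "legacy"),
                             f_range = c(0.5, 800)) {
  method <- match.arg(method)
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  labels <- if (method == "subarea") enumerate_combinations(model)
  rows <- lapply(spectra, function(sp) {
    v <- if (method == "subarea") {
      stats::setNames(subarea_features(sp, model, f_range, labels),
                      paste0("D_", labels))
    } else {
      legacy_features(sp, model, f_range)
    }
    cbind(data.frame(sample_id = attr(v, "sample_id"),
                     repetition = attr(v, "repetition"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[c("sample_id", "repetition")])) {
    stop("duplicate (sample_id, repetition) pairs among spectra")
  }
  if (!is.null(metadata)) {
    out <- merge(out, metadata[c("sample_id", "mu_prime")],
                 by = "sample_id", sort = FALSE)
  }
  out[order(out$sample_id, out$repetition), , drop = FALSE]
}

feature_columns <- function(features) {
  grep("^(D|A)_", names(features), value = TRUE)
}

#' Screen features by one-way ANOVA across samples
#'
#' For each feature column, a one-way analysis of variance tests for
#' between-sample differences over the repeated measurements; features with
#' p below `alpha` are selected as regression candidates. Tukey HSD
#' pairwise comparisons are reported alongside. Features constant over all
#' rows are excluded with a warning.
#'
#' @param features Feature table from [extract_features()] (columns
#'   `sample_id`, `repetition`, feature columns). At least two samples with
#'   at least two repetitions each.
#' @param alpha Selection level (default 0.05).
#' @param tukey Also run Tukey HSD per feature?
#' @return Object of class `feature_screen`: data frame `table` (feature,
#'   F, p, selected), `selected` labels, optional `tukey` list, `alpha`.
#' @export
screen_features <- function(features, alpha = 0.05, tukey = TRUE) {
  cols <- feature_columns(features)
  stopifnot(length(cols) >= 1L, "sample_id" %in% names(features))
  sample <- factor(features$sample_id)
  if (nlevels(sample) < 2L) stop("need at least two samples to screen features")
  if (min(table(sample)) < 2L) stop("need at least two repetitions per sample")
  keep <- vapply(cols, function(cl) stats::var(features[[cl]]) > 0, logical(1L))
  if (any(!keep)) {
    warning("excluding constant feature(s): ", paste(cols[!keep], collapse = ", "))
  }
  cols <- cols[keep]
  fits <- lapply(cols, function(cl) {
    stats::aov(features[[cl]] ~ sample)
  })
  pv <- vapply(fits, function(f) summary(f)[[1L]][["Pr(>F)"]][1L], numeric(1L))
  Fv <- vapply(fits, function(f) summary(f)[[1L]][["F value"]][1L], numeric(1L))
  tab <- data.frame(feature = cols, F = Fv, p = pv, selected = pv < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(table = tab, selected = cols[tab$selected], alpha = alpha,
              tukey = if (tukey) {
                stats::setNames(lapply(fits, stats::TukeyHSD), cols)
              })
  class(out) <- "feature_screen"
  out
}

#' @export
print.feature_screen <- function(x, ...) {
  cat("One-way ANOVA feature screen (alpha =", x$alpha, ")\n")
  print(x$table, digits = 4)
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
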