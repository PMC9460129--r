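# Piecewise log-linear vibrotactile firing-threshold curves for the four
# glabrous-skin mechanoreceptor populations, and the amplitude band structure
# ("firing combinations") they induce at each stimulus frequency.

#' Canonical mechanoreceptor order
#'
#' Fixed ordering of the four glabrous-skin mechanoreceptor populations used
#' everywhere in the package: Merkel disks (SA I), Ruffini endings (SA II),
#' Meissner corpuscles (FA I) and Pacinian corpuscles (FA II). Firing
#' combinations are labelled by concatenating members in this order.
#'
#' @format Character vector of length 4.
#' @export
RECEPTORS <- c("SAI", "SAII", "FAI", "FAII")

#' Construct a mechanoreceptor threshold model
#'
#' A threshold model holds, for each receptor, an ordered list of log-linear
#' segments `threshold(f) = slope * log10(f) + intercept` (dB re 1 micrometre
#' peak displacement) tiling the receptor's frequency domain. A receptor is
#' treated as never firing (threshold +Inf) outside its domain.
#'
#' @param segments Named list (names from [RECEPTORS]); each element a
#'   data frame with columns `slope` (dB per decade), `intercept` (dB),
#'   `f_lo`, `f_hi` (Hz), rows ordered by frequency and tiling the domain
#'   without gaps.
#' @param open_lower Named logical: is the receptor's domain start exclusive?
#'   Defaults to `FALSE` for every receptor not named.
#' @param continuity_tol Maximum allowed jump (dB) between adjacent segments
#'   at a shared breakpoint; printed coefficients are rounded, so a small
#'   mismatch is tolerated.
#' @return An object of class `threshold_model`.
#' @seealso [default_threshold_model()] for the packaged curves.
#' @export
threshold_model <- function(segments, open_lower = NULL, continuity_tol = 0.05) {
  stopifnot(is.list(segments), length(segments) >= 1L)
  if (is.null(names(segments)) || anyNA(names(segments)) ||
      !all(names(segments) %in% RECEPTORS)) {
    stop("'segments' must be a named list with names among: ",
         paste(RECEPTORS, collapse = ", "))
  }
  open <- stats::setNames(rep(FALSE, length(segments)), names(segments))
  if (!is.null(open_lower)) open[names(open_lower)] <- open_lower
  for (r in names(segments)) {
    s <- segments[[r]]
    stopifnot(is.data.frame(s),
              all(c("slope", "intercept", "f_lo", "f_hi") %in% names(s)))
    s <- s[order(s$f_lo), , drop = FALSE]
    if (any(s$f_lo <= 0) || any(s$f_lo >= s$f_hi)) {
      stop("receptor ", r, ": segments need 0 < f_lo < f_hi")
    }
    if (nrow(s) > 1L) {
      if (any(abs(s$f_hi[-nrow(s)] - s$f_lo[-1L]) > 1e-9)) {
        stop("receptor ", r, ": segments must tile the domain without gaps")
      }
      fb <- s$f_hi[-nrow(s)]
      a <- s$slope[-nrow(s)] * log10(fb) + s$intercept[-nrow(s)]
      b <- s$slope[-1L] * log10(fb) + s$intercept[-1L]
      if (any(abs(a - b) > continuity_tol)) {
        stop("receptor ", r, ": discontinuity above ", continuity_tol,
             " dB at breakpoint ", fb[which.max(abs(a - b))], " Hz")
      }
    }
    segments[[r]] <- s
  }
  structure(list(segments = segments, open_lower = open),
            class = "threshold_model")
}

#' Packaged mechanoreceptor threshold model
#'
#' The piecewise log-linear firing-threshold curves used throughout the
#' package: FA I on \[0.5, 67\] Hz (three segments), FA II on (20, 800\] Hz
#' (two segments, V-shaped with its minimum near 238 Hz), SA I on
#' \[0.5, 120\] Hz (two segments) and SA II on \[0.5, 400\] Hz (three
#' segments). The same model ships as YAML in
#' `system.file("extdata", "threshold_model.yaml", package = "vibrotact")`.
#'
#' @return A `threshold_model`.
#' @examples
#' m <- default_threshold_model()
#' evaluate_threshold(m, "FAI", 1)   # 53.91 dB
#' @export
default_threshold_model <- function() {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 4L, byrow = TRUE)
    data.frame(slope = m[, 1L], intercept = m[, 2L], f_lo = m[, 3L], f_hi = m[, 4L])
  }
  threshold_model(
    segments = list(
      FAI  = seg(-17.22,  53.91,   0.5,  10.13,
                 -12.12,  48.78,  10.13, 14.73,
                  0.2373, 34.34,  14.73, 67),
      FAII = seg(-38.64,  64.57,  20,    237.64,
                  24.93, -86.48, 237.64, 800),
      SAI  = seg(-10.90,  32.77,   0.5,  20.55,
                  9.195,   6.390, 20.55, 120),
      SAII = seg(-17.22,  53.90,   0.5,  10.13,
                 -12.12,  48.78,  10.13, 128.51,
                 -0.6747, 24.64, 128.51, 400)
    ),
    open_lower = c(FAII = TRUE)
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Mechanoreceptor threshold model\n")
  for (r in intersect(RECEPTORS, names(x$segments))) {
    s <- x$segments[[r]]
    lo <- if (isTRUE(x$open_lower[[r]])) "(" else "["
    cat(sprintf("  %-4s %s%g, %g] Hz, %d segment%s\n", r, lo, s$f_lo[1L],
                s$f_hi[nrow(s)], nrow(s), if (nrow(s) > 1L) "s" else ""))
  }
  invisible(x)
}

#' Frequency domain of a receptor
#'
#' @param model A `threshold_model`.
#' @param receptor One of [RECEPTORS] present in the model.
#' @return Numeric `c(f_lo, f_hi)` with attribute `open_lower`.
#' @export
receptor_domain <- function(model, receptor) {
  s <- model$segments[[match.arg(receptor, names(model$segments))]]
  structure(c(s$f_lo[1L], s$f_hi[nrow(s)]),
            open_lower = isTRUE(model$open_lower[[receptor]]))
}

#' Evaluate a receptor's firing threshold
#'
#' Returns `slope * log10(f) + intercept` of the segment containing `f`, or
#' `NA` outside the receptor's domain (callers treat `NA` as +Inf: the
#' receptor never fires there). At an interior breakpoint the earlier segment
#' is used; the construction guarantees the two readings agree within the
#' continuity tolerance.
#'
#' @param model A `threshold_model`.
#' @param receptor Receptor id.
#' @param f Vector of frequencies (Hz), all > 0.
#' @return Numeric vector of thresholds in dB, `NA` where out of domain.
#' @examples
#' m <- default_threshold_model()
#' evaluate_threshold(m, "SAI", 1)        # 32.77
#' evaluate_threshold(m, "FAII", 10)      # NA: below the FA II domain
#' @export
evaluate_threshold <- function(model, receptor, f) {
  stopifnot(inherits(model, "threshold_model"))
  receptor <- match.arg(receptor, names(model$segments))
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0)) {
    stop("'f' must be finite and positive (Hz)")
  }
  s <- model$segments[[receptor]]
  dom <- receptor_domain(model, receptor)
  inside <- f <= dom[2L] & (if (attr(dom, "open_lower")) f > dom[1L] else f >= dom[1L])
  out <- rep(NA_real_, length(f))
  if (any(inside)) {
    # first segment whose [f_lo, f_hi] contains f; ties at breakpoints go to
    # the earlier segment
    idx <- findInterval(f[inside], s$f_lo[-1L], left.open = TRUE) + 1L
    out[inside] <- s$slope[idx] * log10(f[inside]) + s$intercept[idx]
  }
  out
}

threshold_matrix <- function(model, f) {
  recs <- intersect(RECEPTORS, names(model$segments))
  m <- vapply(recs, function(r) evaluate_threshold(model, r, f),
              numeric(length(f)))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L, dimnames = list(NULL, recs))
  m
}

#' Label a firing combination
#'
#' Concatenates receptor names in the canonical order SA I, SA II, FA I,
#' FA II; the full four-member set is labelled `"ALL"`.
#'
#' @param members Character vector, subset of [RECEPTORS], nonempty.
#' @return Single label string, e.g. `"SAISAIIFAI"`.
#' @export
combo_label <- function(members) {
  members <- unique(members)
  stopifnot(length(members) >= 1L, all(members %in% RECEPTORS))
  if (length(members) == 4L) return("ALL")
  paste(RECEPTORS[RECEPTORS %in% members], collapse = "")
}

#' Amplitude band structure at one frequency
#'
#' At frequency `f`, the thresholds of the receptors whose domains contain
#' `f`, sorted ascending, slice the amplitude axis into contiguous slabs.
#' Slab k runs from the k-th threshold to the (k+1)-th (the topmost is
#' unbounded) and is labelled by the set of receptors whose thresholds lie at
#' or below its lower edge — the receptors that fire for a stimulus falling
#' in that slab. Equal thresholds produce a zero-height slab, kept so that
#' combination labels are stable; ties are ordered by the canonical receptor
#' order.
#'
#' @param model A `threshold_model`.
#' @param f Scalar frequency in \[0.5, 800\] Hz.
#' @param tie_tol Thresholds closer than this (dB) are treated as tied and
#'   ordered canonically. The default 0.05 dB matches the rounding of the
#'   printed coefficients; without it, rounding noise creates spurious
#'   hair-width band orderings near curve intersections (e.g. a transient
#'   FA I-below-SA II inversion just above 14.73 Hz).
#' @return Data frame with columns `lower`, `upper` (dB; last `upper` is
#'   `Inf`) and `combo` (label); attribute `members` holds the member sets.
#'   Tied thresholds yield (near-)zero-height slabs, kept so labels are
#'   stable.
#' @examples
#' band_structure(default_threshold_model(), 50)
#' @export
band_structure <- function(model, f, tie_tol = 0.05) {
  stopifnot(inherits(model, "threshold_model"), length(f) == 1L, is.finite(f))
  if (f < 0.5 || f > 800) stop("'f' must lie in [0.5, 800] Hz")
  thr <- threshold_matrix(model, f)[1L, ]
  thr <- thr[!is.na(thr)]
  if (length(thr) == 0L) {
    stop("no receptor threshold is defined at f = ", f, " Hz")
  }
  canon <- match(names(thr), RECEPTORS)
  ord <- threshold_order(thr, canon, tie_tol)
  lower <- cummax(thr[ord])  # monotone slab edges; ties flattened upward
  n <- length(ord)
  members <- lapply(seq_len(n), function(k) names(thr)[ord[seq_len(k)]])
  out <- data.frame(
    lower = unname(lower),
    upper = c(unname(lower)[-1L], Inf),
    combo = vapply(members, combo_label, character(1L)),
    stringsAsFactors = FALSE
  )
  attr(out, "members") <- members
  out
}

# ascending threshold order with near-ties (<= tie_tol apart) regrouped into
# canonical receptor order
threshold_order <- function(vals, canon, tie_tol = 0.05) {
  ord <- order(vals, canon)
  grp <- cumsum(c(1, diff(vals[ord]) > tie_tol))
  ord[order(grp, canon[ord])]
}

#' Enumerate firing combinations over a frequency grid
#'
#' Union of the band-structure combination labels over a grid of
#' frequencies. With the packaged model and a log-spaced grid of at least
#' 1000 points over \[0.5, 800\] Hz this yields exactly eight labels:
#' SAI, SAISAII, SAISAIIFAI, FAII, SAIFAII, SAIIFAII, SAISAIIFAII, ALL.
#'
#' @param model A `threshold_model`.
#' @param f_grid Nonempty vector of frequencies in \[0.5, 800\] Hz.
#' @return Character vector of labels, ordered by member count then by the
#'   canonical receptor order.
#' @export
enumerate_combinations <- function(model, f_grid = log_frequency_grid()) {
  if (length(f_grid) == 0L) stop("'f_grid' is empty")
  thr <- threshold_matrix(model, f_grid)
  recs <- colnames(thr)
  canon <- match(recs, RECEPTORS)
  seen <- new.env(parent = emptyenv())
  labs <- character(0)
  for (i in seq_len(nrow(thr))) {
    ti <- thr[i, ]
    def <- which(!is.na(ti))
    if (length(def) == 0L) {
      stop("no receptor threshold is defined at f = ", f_grid[i], " Hz")
    }
    ord <- def[threshold_order(ti[def], canon[def])]
    key <- paste(ord, collapse = ".")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      labs <- union(labs, vapply(seq_along(ord), function(k) {
        combo_label(recs[ord[seq_len(k)]])
      }, character(1L)))
    }
  }
  order_combo_labels(labs)
}

#' Log-spaced frequency grid
#'
#' @param n Number of points.
#' @param f_range Frequency range in Hz.
#' @return Numeric vector of `n` log-spaced frequencies.
#' @export
log_frequency_grid <- function(n = 2000L, f_range = c(0.5, 800)) {
  g <- 10^seq(log10(f_range[1L]), log10(f_range[2L]), length.out = n)
  g[1L] <- f_range[1L]
  g[n] <- f_range[2L]
  g
}

# deterministic display order: fewer members first, then canonical order
order_combo_labels <- function(labels) {
  members <- lapply(labels, combo_members)
  size <- lengths(members)
  key <- vapply(members, function(m) {
    sum(2^(match(m, RECEPTORS) - 1L))
  }, numeric(1L))
  labels[order(size, key)]
}

combo_members <- function(label) {
  if (identical(label, "ALL")) return(RECEPTORS)
  out <- character()
  # greedy scan in canonical order; labels are canonical concatenations
  rest <- label
  for (r in RECEPTORS) {
    if (startsWith(rest, r)) {
      # "SAI" prefixes "SAII": prefer the longer receptor name when it matches
      cand <- RECEPTORS[startsWith(rest, RECEPTORS)]
      take <- cand[which.max(nchar(cand))]
      out <- c(out, take)
      rest <- substring(rest, nchar(take) + 1L)
    }
    if (!nzchar(rest)) break
  }
  if (nzchar(rest)) stop("not a canonical combination label: ", label)
  out
}

#' Write a threshold model to YAML
#'
#' Serialises the model as `receptor -> list of {slope, intercept, f_lo,
#' f_hi}` plus an `open_lower` list, the schema used by the packaged default
#' in `inst/extdata/threshold_model.yaml`.
#'
#' @param model A `threshold_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  obj <- list(
    receptors = lapply(model$segments, function(s) {
      lapply(seq_len(nrow(s)), function(i) as.list(s[i, , drop = FALSE]))
    }),
    open_lower = as.list(model$open_lower[model$open_lower])
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a threshold model from YAML
#'
#' @param path YAML file written by [write_threshold_model()].
#' @return A `threshold_model`.
#' @export
read_threshold_model <- function(path) {
  obj <- yaml::read_yaml(path)
  segments <- lapply(obj$receptors, function(segs) {
    do.call(rbind, lapply(segs, as.data.frame))
  })
  open_lower <- if (length(obj$open_lower)) {
    stats::setNames(unlist(obj$open_lower), names(obj$open_lower))
  }
  threshold_model(segments, open_lower = open_lower)
}
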