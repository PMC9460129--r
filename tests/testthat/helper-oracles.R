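# Independent oracles used by the test suite. They re-derive quantities from
# first principles (direct piecewise formulas, rectangle counting, normal
# equations) and never call the code paths they check.

# The four published piecewise threshold curves, written out directly.
# Returns a named vector (SAI, SAII, FAI, FAII); NA outside a domain.
oracle_threshold <- function(f) {
  stopifnot(length(f) == 1L, f > 0)
  u <- log10(f)
  fai <- if (f >= 0.5 && f <= 10.13) -17.22 * u + 53.91
    else if (f > 10.13 && f <= 14.73) -12.12 * u + 48.78
    else if (f > 14.73 && f <= 67) 0.2373 * u + 34.34
    else NA_real_
  faii <- if (f > 20 && f <= 237.64) -38.64 * u + 64.57
    else if (f > 237.64 && f <= 800) 24.93 * u - 86.48
    else NA_real_
  sai <- if (f >= 0.5 && f <= 20.55) -10.90 * u + 32.77
    else if (f > 20.55 && f <= 120) 9.195 * u + 6.390
    else NA_real_
  saii <- if (f >= 0.5 && f <= 10.13) -17.22 * u + 53.90
    else if (f > 10.13 && f <= 128.51) -12.12 * u + 48.78
    else if (f > 128.51 && f <= 400) -0.6747 * u + 24.64
    else NA_real_
  c(SAI = sai, SAII = saii, FAI = fai, FAII = faii)
}

# Step-function lookup of a binned dB spectrum: bin edges are midpoints
# between centers (recomputed here, independently of the package).
oracle_spectrum_lookup <- function(frequency, db) {
  n <- length(frequency)
  mid <- (frequency[-1L] + frequency[-n]) / 2
  edges <- c(frequency[1L] - (mid[1L] - frequency[1L]), mid,
             frequency[n] + (frequency[n] - mid[n - 1L]))
  function(f) db[findInterval(f, edges, rightmost.closed = TRUE)]
}

# Brute-force rectangle-counting oracle for the firing-combination subarea
# features, on a fine (log10 f x dB) grid. A grid point (u, v) belongs to
# combination {r : L_r(10^u) <= v} and is counted iff L0(10^u) < v <= s(10^u).
oracle_subarea_grid <- function(frequency, db, f_range = c(0.5, 800),
                                n_u = 2000L, n_v = 1500L) {
  lookup <- oracle_spectrum_lookup(frequency, db)
  u_edges <- seq(log10(f_range[1L]), log10(f_range[2L]), length.out = n_u + 1L)
  du <- diff(u_edges[1:2])
  u_mid <- u_edges[-1L] - du / 2
  v_lo <- -35
  v_hi <- max(db) + 1
  dv <- (v_hi - v_lo) / n_v
  v_mid <- v_lo + (seq_len(n_v) - 0.5) * dv
  acc <- new.env(parent = emptyenv())
  recs <- c("SAI", "SAII", "FAI", "FAII")
  for (j in seq_len(n_u)) {
    f <- 10^u_mid[j]
    thr <- oracle_threshold(f)
    def <- which(!is.na(thr))
    if (length(def) == 0L) next
    L0 <- min(thr[def])
    s <- lookup(f)
    inside <- v_mid > L0 & v_mid <= s
    if (!any(inside)) next
    code <- integer(n_v)
    for (r in def) code <- code + as.integer(v_mid >= thr[r]) * 2L^(r - 1L)
    tab <- table(code[inside])
    for (cd in names(tab)) {
      ci <- as.integer(cd)
      if (ci == 0L) next  # below every threshold yet above L0: impossible
      members <- recs[bitwAnd(ci, 2L^(0:3)) > 0L]
      lab <- if (length(members) == 4L) "ALL" else paste(members, collapse = "")
      acc[[lab]] <- (if (is.null(acc[[lab]])) 0 else acc[[lab]]) +
        tab[[cd]] * du * dv
    }
  }
  unlist(as.list(acc))
}

# Fine Riemann-sum oracle for a flat dB level over [f_lo, f_hi]: slab areas
# per combination from the direct formulas (midpoint rule in u).
oracle_flat_subareas <- function(level_db, f_lo, f_hi, n = 200000L) {
  u <- seq(log10(f_lo), log10(f_hi), length.out = n + 1L)
  du <- diff(u[1:2])
  um <- u[-1L] - du / 2
  acc <- new.env(parent = emptyenv())
  for (j in seq_len(n)) {
    thr <- oracle_threshold(10^um[j])
    thr <- sort(thr[!is.na(thr)])
    if (length(thr) == 0L || level_db <= thr[1L]) next
    upper <- c(thr[-1L], Inf)
    h <- pmax(0, pmin(level_db, upper) - thr)
    for (k in which(h > 0)) {
      members <- names(thr)[seq_len(k)]
      ord <- match(members, c("SAI", "SAII", "FAI", "FAII"))
      members <- members[order(ord)]
      lab <- if (length(members) == 4L) "ALL" else paste(members, collapse = "")
      acc[[lab]] <- (if (is.null(acc[[lab]])) 0 else acc[[lab]]) + h[k] * du
    }
  }
  unlist(as.list(acc))
}

# Random piecewise-constant dB spectrum (smoothed random walk) covering the
# full threshold band, for oracle-equivalence checks.
random_db_spectrum <- function(seed, n_bins = 1200L) {
  set.seed(seed)
  f <- seq(0.4, 805, length.out = n_bins)
  walk <- cumsum(rnorm(n_bins, 0, 1.5))
  db <- 10 + as.numeric(stats::filter(walk, rep(1 / 25, 25), sides = 2L))
  db[is.na(db)] <- 10
  db <- pmax(pmin(db, 55), -40)
  db_spectrum(f, db, sample_id = paste0("rand", seed))
}

# Normal-equation OLS oracle.
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Agreement between a clustering and planted membership (best label
# matching for k = 2).
cluster_agreement <- function(assigned, truth) {
  stopifnot(length(assigned) == length(truth))
  a <- mean(assigned == truth)
  b <- mean((3L - assigned) == truth)
  max(a, b)
}
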