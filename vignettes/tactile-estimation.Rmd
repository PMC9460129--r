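---
title: "Estimating tactile impressions from tracing vibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tactile impressions from tracing vibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrotact)
```

## The estimation problem

When a compliant sensor (or a fingertip) traces a textured surface, the
stick–slip interaction excites vibrations whose spectral content carries the
information humans use to judge texture. The skin does not pass this signal
on unchanged: four mechanoreceptor populations — Merkel disks (SA I),
Ruffini endings (SA II), Meissner corpuscles (FA I) and Pacinian corpuscles
(FA II) — act as band filters, each firing only when the stimulus amplitude
at a frequency exceeds that receptor's threshold. `vibrotact` implements a
complete pipeline from raw tracing vibrations to predicted sensory scores
built around this perceptibility idea:

1. **Calibration.** Strain-gauge voltage is converted to vertical
   displacement by the sensor's linear calibration
   $d = -1409.4\,V + 710.35$ (micrometres from volts). The constant term is
   the static preload of the leaf spring, not vibration; it lands in the DC
   bin and is removed before spectral analysis.
2. **Spectrum.** The displacement trace is mean-removed, Hamming-windowed
   and transformed to a single-sided amplitude spectrum, scaled by the
   window's coherent gain so a sinusoid's peak bin reports its time-domain
   amplitude. The spectrum is then viewed in dB re 1 µm peak.
3. **Features.** The region between the dB spectrum and the lowest receptor
   threshold is partitioned into *firing-combination subareas* $D_i$: at
   each frequency the sorted thresholds slice the amplitude axis into
   slabs, each labelled by the set of receptors that would fire there. With
   the packaged threshold model exactly eight combinations arise (SAI,
   SAISAII, SAISAIIFAI, FAII, SAIFAII, SAIIFAII, SAISAIIFAII, ALL).
4. **Sensory targets.** Semantic-differential panel scores (seven-step
   unipolar scale, ten adjectives) are clustered by subject (Ward linkage on
   Euclidean distances), each cluster is summarised by correlation-matrix
   PCA with the eigenvalue > 1 rule, and per-sample mean PC scores become
   regression targets.
5. **Model selection.** Four regression families — linear, logarithmic
   ($\log_{10}$ of each regressor), two-variable interaction
   ($x_i, x_j, x_i x_j$, each with its own coefficient) and single-variable
   polynomial (powers $1..a$) — are enumerated exhaustively over the
   screened features plus the dynamic friction coefficient $\mu'$, fitted by
   OLS, and scored by leave-one-sample-out mean squared error.

## The threshold model

Each receptor's firing threshold is piecewise log-linear,
$L(f) = s\,\log_{10} f + c$ in dB, over a bounded domain: FA I on
[0.5, 67] Hz (three segments), FA II on (20, 800] Hz (two segments, V-shaped
with its minimum near 238 Hz, around −27 dB), SA I on [0.5, 120] Hz and
SA II on [0.5, 400] Hz. Outside its domain a receptor is treated as never
firing (threshold $+\infty$). The logarithm is base 10 throughout — the
convention of dB-vs-log-frequency threshold charts — and threshold units are
dB re 1 µm peak displacement, the same scale on which spectra are compared.
The FA II domain opens *exclusively* at 20 Hz; all other endpoints are
inclusive.

```{r}
m <- default_threshold_model()
m
evaluate_threshold(m, "FAI", 1)    # intercept: the log term vanishes at 1 Hz
band_structure(m, 50)
```

Two numerical conventions matter here.

* **Continuity tolerance.** The published segment coefficients are rounded,
  so adjacent segments agree at shared breakpoints only within about
  0.05 dB. Construction enforces (and tests verify) continuity at that
  tolerance.
* **Tie handling.** The same rounding makes some curves cross in
  hair-width slivers — the FA I third segment dips ~0.003 dB below the
  SA II curve for ~0.014 Hz above the 14.73 Hz breakpoint — which would
  create spurious band orderings on fine grids. `band_structure()`
  therefore treats thresholds within 0.05 dB as tied, orders ties by the
  fixed receptor order (SA I, SA II, FA I, FA II), and flattens slab edges
  monotonically. Tied thresholds still produce (near-)zero-height slabs, so
  the SAISAII combination — bounded below by SA II at 53.90 dB and above by
  FA I at 53.91 dB at low frequency — exists with a small but honest area.
  With these conventions the combination set is stable from $10^3$ to
  $10^5$ grid points.

## Subarea integration

`subarea_features()` integrates in $(\log_{10} f) \times \mathrm{dB}$
coordinates: thresholds are straight lines on that chart, and equal
perceptual weight per decade is the natural reading of the log-frequency
axis (linear-frequency weighting would let the 400–800 Hz octave dominate).
Each spectrum bin contributes a rectangle of its width in decades; the
vertical column from the lowest threshold to the spectrum level is cut by
the band structure into slabs, and each slab accrues to its combination.
Consequences, all enforced by tests:

* $\sum_i D_i$ equals the total area between spectrum and lowest threshold
  exactly (the slabs partition the column);
* features are non-negative and can all be zero (a spectrum below every
  threshold fires nothing);
* per-bin rectangle quadrature is used; at the default FFT resolution
  (0.305 Hz bins) refinement to trapezoids changes areas by far less than
  the 1% oracle tolerance used in tests.

The slab (horizontal-band) decomposition, rather than assigning whole
columns to one combination, is what produces intermediate combinations such
as SAISAII and SAIFAII — only the slab reading reproduces all eight labels.

The baseline `legacy_features()` ignores simultaneous firing: the frequency
axis is partitioned by *which* receptor holds the lowest threshold, and the
whole over-threshold column accrues to that receptor's pooled band. The
original construction of this baseline is not published in full, so the
reconstruction follows that rule and is labelled "A-method (reconstructed)"
in outputs. One honest consequence: under the packaged curves the lowest
threshold belongs to SA I on [0.5, 20] Hz and to FA II on (20, 800] Hz, so
only those two pooled areas are structurally non-zero; the function reports
one pooled area per receptor (four stable keys) rather than forcing a
particular count. Both partitions cover the same region, so subarea and
legacy features have identical sums — a useful cross-check.

## Signal-processing choices

* `n_fft` defaults to 32768 ($2^{15}$): a 3 s trace at 10 kHz (30 000
  samples) is mean-removed, windowed over its length and zero-padded.
  Traces longer than `n_fft` are reduced to their central portion, where
  tracing is in steady state.
* Single-sided scaling divides by the window's coherent gain
  ($\sum w / 2$ per side), so bin-centred sinusoids are recovered within
  1% (tested, and cross-checked by an exact discrete Parseval identity on
  the reported amplitudes).
* Zero amplitudes map to a configurable dB floor (default −120 dB) so the
  dB view is finite; the floor is far below every threshold and contributes
  nothing to features.
* Bin 0 (DC) is excluded from feature integration; the 710.35 µm
  calibration offset is static preload.

## Sensory analysis choices

Subjects are clustered on their flattened sample × word score vectors with
`hclust(method = "ward.D2")` — Ward's criterion on unsquared Euclidean
distances. PCA is run on the correlation matrix of (subject, sample) × word
observations *within a cluster*; that observation layout is the only one
that yields per-subject-per-sample scores that can be averaged into
per-sample targets. Components are retained while eigenvalues exceed 1,
loadings are eigenvectors scaled by $\sqrt{\lambda}$, and no rotation is
applied — the simplest reading of an eigenvalue-rule PCA. Signs are fixed
by making each component's largest-magnitude loading positive; PCA signs
are otherwise arbitrary and all comparisons are made up to sign. The
default cluster count is $k = 2$, configurable.

## Regression and selection choices

* `p_max` defaults to 5 regressors: fitting on seven training samples with
  five slopes plus an intercept leaves one residual degree of freedom.
* `a_max` defaults to 3 (cubic), matching the largest published polynomial.
* The interaction family estimates an independent coefficient for the
  product term.
* The cross-validation metric is mean squared error by default; RMSE is
  available and labelled in output (`metric`), since "average error" alone
  does not disambiguate the two.
* Infeasible specifications — logarithms of non-positive features, more
  coefficients than training rows, rank-deficient designs, or any
  infeasible fold — are skipped and their cells reported as `NA`, never
  fatal errors: with only eight samples, infeasibility is routine, not
  exceptional.
* Ties in a cell are broken by fewer estimated parameters, then by the
  lexicographic variable label, then by fixed cell order, making selection
  fully deterministic.
* Standardized coefficients are $\beta'_j = \beta_j\,s_{x_j}/s_y$, computed
  on the transformed (post-log, post-power) design columns.

The five published best-per-target equations ship verbatim in
`evaluate_frozen()` (logarithms base 10; the cubic C1PC2 equation has no
intercept, so it vanishes at zero input). They are the package's only
bridge to the published fits: the measured data behind the published error
tables are not deposited, so those tables are not reproduction targets.

```{r}
evaluate_frozen("C2PC1", c(D_SAISAIIFAI = 1, mu_prime = 1))
```

## What the synthetic generators emulate — and what they do not

`simulate_trace()` is spectral phenomenology: a fundamental at
(tracing speed)/(spatial period) with geometrically rolled-off harmonics,
random phases and white Gaussian noise. Defaults mirror the study
conditions (10 mm/s, 30 mm distance hence 3 s, 10 kHz, 11 repetitions,
eight samples). The default plate set spans fundamental amplitudes over
roughly two decades, a plausible range for textured plastics, so features
exercise the dynamic range the regressions need. The generator does *not*
model contact mechanics, finger compliance, nonstationary stick–slip
bursts, or amplitude-dependent harmonic structure — so passing tests show
the pipeline's correctness on its stated model, not validity on any
particular real material.

`simulate_panel()` plants a two-cluster, two-factor structure: scores are
$4 + \mathbf{l}_w^\top \mathbf{f}_s + \varepsilon$, rounded and clipped to
1..7, with cluster 2's loadings sign-flipped (opposite response polarity)
and subject noise SD defaulting to 1 — about one step of the seven-point
scale, a typical panel repeatability. Rounding and clipping make the planted
structure recoverable but not exactly linear-Gaussian, which is deliberate:
real panels are discrete and bounded. Friction coefficients are drawn
uniformly on [0.2, 1.2].

All generators are deterministic under a seed, record the seed in their
output, and restore the session's random state.

## Problem sizes used by the test suite

The suite checks oracle equivalence of the subarea integration on random
spectra against a brute-force rectangle-counting oracle on a
2000 × 1500 $(\log_{10} f) \times \mathrm{dB}$ grid (1% of total area),
and runs the planted-recovery studies at the study's own scale: 100 seeded
replicates of an eight-sample logarithmic law at noise SD 0.01, and 100
seeded 35-subject panels for cluster recovery. Those sizes keep every
property estimable with comfortable margins while the full suite runs in a
couple of minutes.

## Known limitations

* The legacy baseline is a reconstruction (see above); its absolute values
  should not be compared against the original implementation, only its
  role as a comparison method is preserved.
* The published contribution percentages for the sensory PCA are not
  exactly reproduced by correlation-matrix PCA (eigenvalue/number-of-words
  differs from the printed rate for the first component), suggesting an
  unstated extraction detail in the original analysis; this package
  documents its own convention rather than guessing.
* With eight samples, leave-one-sample-out selection among dozens of
  specifications is honest but high-variance; the planted-recovery studies
  quantify exactly how often the true family wins under the packaged
  conditions, nothing more.
* Threshold curves describe median human perceptibility; individual
  variation in receptor sensitivity is not modelled.
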