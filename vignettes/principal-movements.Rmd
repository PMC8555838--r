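---
title: "Principal movement analysis: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal movement analysis: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one convention was defensible.

## The model

A motion-capture recording of `M` markers at frame rate `fs` gives, per
frame, a posture vector of `3M` coordinates. The analysis treats the time
series of posture vectors as samples from a low-dimensional subspace: most
of the variance of upper-body motion is assumed to be expressible as a
linear combination of a few fixed coordination patterns (*synergies*),
each engaging many markers at once. Principal component analysis is the
estimator of that subspace; its components are *eigenpostures*, and an
eigenposture together with its projection time series
`w_i(t)` — the weight, or activation, of the synergy — is a *principal
movement* (PM).

The pipeline is:

1. **Pelvis referencing.** All markers are expressed relative to the
   pelvis marker per frame, removing whole-body translation. The origin
   marker's coordinates become identically zero and its columns are
   dropped from the posture matrix (see *The 57-column geometry* below).
2. **Anthropometric normalization**, per signer:
   `p_norm(t) = (p(t) − p̄) / d̄`, with `p̄` the signer's mean posture over
   all their recording units and `d̄` the *mean of the per-frame Euclidean
   norms* of the centered vectors. Centering removes differences in mean
   pose; the scale removes body-size differences and gives every signer a
   mean row norm of exactly 1, hence equal contribution to the pooled
   variance. `d̄` is a mean, not a median or an RMS: the normalization is
   defined through the average norm, and the package keeps that reading
   throughout (the stored parameters invert the map exactly).
3. **Decomposition.** SVD of the stacked normalized matrix, *without
   re-centering*: each signer's block is already centered, and
   subtracting a second cross-signer mean would introduce an operation
   the model does not contain. `pma()` asserts that column means are
   negligible and refuses matrices that are not centered. Eigenvalues are
   `d_j^2 / n` (population denominator), so the variance of the weight
   column equals its eigenvalue exactly, and explained-variance fractions
   are eigenvalues over their sum.
4. **Weight filtering.** Weights are low-pass filtered (zero-phase
   Butterworth, defaults below) before any similarity, spectral-report or
   extreme-frame analysis. Filtering is applied independently within each
   recording unit: units are unsynchronized utterances, and a filter run
   across their concatenation would smear unrelated signals into one
   another at the boundaries.
5. **Resynthesis.** `PM_i(t) = p̄ + d̄ · w_i(t) · PC_i` maps a single
   component back to original units for stick-figure/point-light display.
   Comparisons between signers use the *normalized* PM
   (`w_i(t) · PC_i` alone), so that similarity is judged beyond
   anthropometric differences.

### Assumptions

Linearity (synergies combine additively), stationarity of the synergy
*directions* within a cohort (the weights may do anything), and noise that
is broadband while movement is band-limited. None of these are enforced by
the data format; they are what the estimator is consistent under.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| filter cutoff | 6 | Hz | movement power concentrates below 3 Hz with residual up to ~6 Hz; above that is treated as noise |
| filter order | 4 | — | standard biomechanics choice; applied forward-backward, so the effective magnitude is the square of a 4th-order response |
| Welch segment | 4 | s | 0.25 Hz resolution; several segments per recording unit |
| Welch overlap / window | 0.5 / Hann | — | the usual averaged-periodogram trade-off |
| `ev_target` | 0.946 | fraction | retention rule: smallest K whose cumulative explained variance reaches the target; `n_pms` overrides it when the analyst prefers the leave-one-out robustness criterion instead |
| similarity thresholds | 0.7 / 0.5 | — | conventional "high" / "moderate" cosine levels |
| combination threshold | 0.4 | — | a row with no single high match but ≥ 2 entries above this is flagged as a combination of common PMs |
| LOO threshold | 15 | degrees | orientation change below this counts as robust to signer changes |

Explained variance is reported from both raw and filtered weights
(`summary()` shows the two columns side by side): which of the two a
published figure uses is often unstated, and the difference itself is a
useful noise diagnostic.

## Numerical choices

- **Sign convention.** The SVD sign is arbitrary; each component is
  flipped so its largest-magnitude loading is positive. Flipping a
  component together with its weights changes nothing downstream (this is
  tested), so the convention only buys reproducibility.
- **Zero-phase filtering.** The filter is applied forward and backward, so
  there is no phase lag (extreme-frame timing is preserved). The stock
  `signal::filtfilt` starts both passes from a zero state, which corrupts
  the signal ends badly (a constant input comes back visibly wrong near
  the edges). The package therefore runs `signal::butter` coefficients
  through its own forward-backward pass with odd-reflection padding and
  steady-state initial conditions; a constant then passes through at
  machine precision and a 10 s test tone matches the closed-form response
  below to a fraction of a percent.
- **The analytic filter response.** The digital filter is the bilinear
  transform of an analog Butterworth with prewarped cutoff, so its exact
  magnitude is `|H(f)|² = 1/(1 + (tan(πf/fs)/tan(πfc/fs))^(2n))` — not the
  analog `1/(1 + (f/fc)^(2n))`, which is ~15% off in power by 20 Hz at
  250 fps. Tests and `butterworth_gain()` use the exact form.
- **Welch PSD.** Hann-tapered, mean-detrended segments, one-sided density
  scaling: the integral of the PSD over frequency approximates the signal
  variance (checked to 5%). When assessing the band-limitation of
  synthetic weight signals, segments are aligned to recording units
  (segment length = unit length, no overlap): windows straddling the
  boundary between two statistically independent units would see a step
  discontinuity and report spurious broadband power.
- **Ties and degenerate input.** Extreme-weight frames break ties toward
  the earliest frame. Constant (degenerate) signer blocks are rejected at
  normalization (`d̄ = 0` has no meaningful inverse), all-zero PMs are
  rejected by the cosine (undefined similarity), and missing coordinates
  are a hard load-time error — no gap-filling anywhere, because no
  interpolation procedure is part of the model.
- **Cosine similarity on rank-one PM matrices** factorizes as
  `(w_a·w_b)(PC_a·PC_b)/(‖w_a‖‖w_b‖)`; `similarity_matrix()` uses the
  factorized form (exact, and cheap at 30,000 × 57 per PM), while
  `pm_cosine()` flattens matrices literally. The equality of the two
  routes is a test.

## Design decisions that were genuinely open

- **The 57-column geometry.** The reference corpus describes 21 markers
  yet reports 57-column posture matrices, and 57 = 19 × 3, not 21 × 3.
  Dropping the origin marker's identically-zero columns is principled but
  only removes three columns; which further marker (if any) the original
  analysis excluded is not stated, and the package does not guess. It
  resolves the tension by (a) making origin-dropping the default in
  `build_posture_matrix()` and (b) giving the *synthetic* cohort 20
  generic markers (origin + 19 moving), so the default simulated geometry
  is exactly 30,000 × 57 per signer while real 21-marker data produces
  the honest 60 columns.
- **Unsigned angles and cosines by default.** Component signs carry no
  information, so orientation agreement is measured on axes
  (`|cos|`); a signed mode exists for auditing.
- **Same-rank matching in the leave-one-out analysis** (PC_i versus
  PC_i), because the question is whether *the i-th component* keeps its
  orientation; a best-match variant is reported alongside for diagnosing
  rank swaps, which otherwise masquerade as ~90° changes.
- **Cross-projection variance** is the sum over the first N components of
  the variance of the projection coefficients. This is the only reading
  under which the directed ratio is bounded by 1 (PCA optimality) — the
  bound is property-tested — and under which "closer to 1 means more
  similar" is meaningful. Whether one normalizes by total variance first
  is cosmetic: it cancels in the ratio.
- **Retention rule.** The variance rule (smallest K reaching the target)
  is computable from a single fit, so it is the default; the robustness
  rule needs the full leave-one-out analysis, which the package also
  provides for users who prefer it.

## What the generator emulates — and what it does not

`generate_cohort()` plants: an orthonormal K-dimensional basis in the
analysis coordinates; per-signer weight signals that are white noise
low-passed at 3 Hz (the 4th-order roll-off leaves visible power up to
about 6 Hz, matching the spectral picture the filter defaults assume),
with geometrically decaying variances made *exact* by decorrelating and
rescaling, so that planted variances are recoverable to machine precision;
per-signer mean-posture offsets and log-normal uniform scales (so
normalization has real work to do); optional within-subspace rotations or
component permutations per signer (so individual PMs can be combinations
or reorderings of common ones); independent weight stretches per recording
unit (units are separate utterances); and white Gaussian noise in the
pelvis-referenced coordinates at a configured SNR. Noise is applied in the
*referenced* frame deliberately: i.i.d. noise on the pelvis marker itself
would, after referencing, inject a common-mode term correlated across all
markers, which is not the white-noise model the filter rationale assumes.
The pelvis instead gets its own smooth trajectory, so referencing is
exercised nontrivially.

What it does not emulate: articulated-skeleton constraints (bone lengths
are not preserved — frames are unconstrained marker clouds), linguistic
content or any structured nonstationarity, marker occlusions/gaps, soft
tissue artifact, and non-white sensor noise. Passing recovery tests on
synthetic cohorts therefore demonstrates correctness of the *estimator
chain*, not that real signing is 8-dimensional: on real data the
practitioner still owns the judgment of how many components are
movement rather than artifact, using the spectral reports and the
robustness analysis.

## Problem sizes

The default synthetic geometry mirrors the reference corpus: 6 signers ×
24 units × 5 s × 250 fps → 30,000 × 57 per signer, 180,000 × 57 pooled.
End-to-end checks (geometry, planted-subspace recovery at 20 dB) run at
this full size; unit tests use miniature cohorts (tens of frames, a
handful of markers) because every property tested is size-invariant, and
the leave-one-out and determinism checks use mid-size cohorts
(5,000–7,500 frames per signer) — enough for stable spectra while keeping
the suite quick.

## Known limitations

- C3D input is not supported (binary format; no parser in the package's
  dependency set) — convert to TRC or CSV.
- PCA is a linear, second-order method: synergies that combine
  nonlinearly, or that differ between signers only in higher-order
  statistics, are invisible to it; no component rotation (varimax etc.)
  is offered.
- The leave-one-out angle is a *joint* property of cohort composition:
  with per-signer normalization equalizing contributions, a single
  signer's deviating axes move the pooled components by roughly the
  deviation divided by the number of signers. Large planted deviations in
  one signer of a balanced cohort therefore produce modest leave-one-out
  angles; the diagnostic is most sensitive when a deviating signer also
  dominates the variance in the affected components.
- Segment bookkeeping stores 1-based inclusive row ranges (R convention).
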