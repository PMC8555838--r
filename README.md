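# signsynergy

Principal movement analysis of continuous upper-body motion capture, built
for the study of postural synergies in sign language production (and any
other setting where many markers move together in a few coordinated
patterns).

Continuous signing engages dozens of kinematic degrees of freedom, yet
signers do not appear to control each one independently: a small number of
coordinated patterns — *synergies* — may underlie most of the motion. This
package operationalizes that question. Given multi-signer recordings of 3D
marker trajectories, it decomposes posture into **principal movements
(PMs)**: principal components of the posture-vector time series, each an
"eigenposture" (a fixed pattern of correlated marker displacements)
animated by a weight signal `w_i(t)`.

## The method

For each signer, every frame is a posture vector
`p(t) = [x1, y1, z1, ..., xM, yM, zM]` of pelvis-referenced marker
coordinates. A two-step anthropometric normalization removes body-size and
mean-pose differences:

    p_norm(t) = (p(t) - p̄) / d̄

where `p̄` is the signer's mean posture and `d̄` the mean Euclidean norm of
the centered posture vectors, so every signer contributes equal variance
to the cohort. PCA (by SVD, without re-centering) of the stacked
normalized matrix yields orthonormal components `PC_i`, eigenvalues /
explained-variance fractions, and weights `w_i(t) = p_norm(t) · PC_i`,
which are low-pass filtered (zero-phase 4th-order Butterworth, 6 Hz) to
suppress measurement noise. A PM is resynthesized in original units as

    PM_i(t) = p̄ + d̄ · w_i(t) · PC_i.

Three comparison procedures probe how shared the synergies are:

- **Leave-one-out robustness** — the angular change of each `PC_i` when
  one signer is removed before refitting (≤ 15° counts as robust);
- **Cosine similarity** between PMs (flattened normalized trajectory
  matrices), comparing each signer's individual PMs with the cohort's
  common PMs, including rank-permutation and combination diagnostics;
- **Cross-projection similarity** — the variance of one signer's
  movements captured by another signer's leading `N` components relative
  to their own, symmetrized over both directions.

A synthetic cohort generator with planted synergy structure (known basis,
band-limited weight dynamics, per-signer anthropometric transforms,
white coordinate noise at a configured SNR) provides ground truth for
validating every stage.

## Worked example

```r
library(signsynergy)

cfg <- cohort_config(n_signers = 4, n_trials = 8, trial_s = 5, seed = 7)
sim <- simulate_cohort(cfg)     # generate -> reference -> assemble -> normalize
fit <- pma(sim$cohort)          # the central fit
summary(fit, n_show = 10)
#> Principal movement analysis: 40000 frames, 4 signer(s)
#> Retained 6 PMs (cumulative EV target 94.6%)
#>
#>  pm ev_pct cum_ev_pct ev_pct_filtered
#>   1  40.31      40.31           40.66
#>   2  24.18      64.49           24.44
#>   3  14.51      79.00           14.60
#>   4   8.72      87.72            8.79
#>   5   5.24      92.95            5.25
#>   6   3.15      96.11            3.17
#>   7   1.90      98.00            1.90
#>   8   1.15      99.15            1.14
#>   9   0.02      99.17            0.00
#>  10   0.02      99.18            0.00
```

Six PMs already pass the 94.6% cumulative explained-variance target; the
planted eight carry 99.15%, and the remainder is measurement noise (the
drop after PM8 is three orders of magnitude). The fit recovers the planted
synergy basis to a fraction of a degree:

```r
max(principal_angles(sim$truth$basis, coef(fit)[, 1:8]))
#> 0.24   # degrees
```

Leave-one-out robustness and cross-signer subspace similarity:

```r
loo_robustness(sim$cohort, n_pms = 8, fit_full = fit)
#> <loo_robustness> 4 signer(s) x 8 PMs (threshold 15 deg)
#>    PM1 PM2 PM3 PM4 PM5 PM6 PM7 PM8
#> s1   0   0 0.1 0.1 0.1 0.1 0.1 0.1
#> ...
#> all components robust

fits <- lapply(signer_ids(sim$cohort),
               function(id) pma(subset_cohort(sim$cohort, id)))
names(fits) <- signer_ids(sim$cohort)
cross_projection_curve(fits, n_max = 8)$mean[8]
#> 1      # signers share one synergy subspace by construction
```

Individual PMs are resynthesized and exported as point-light displays with
`pm_trajectory()` + `export_pld()`; `run_pipeline(pipeline_config(...))`
executes every stage (common and per-signer decompositions, spectra, all
three comparisons, report tables) in one deterministic call.

Real recordings enter through `read_trial()` (TRC or wide CSV; one file
per recording unit), followed by `reference_to_origin()`,
`extract_segment()`, `build_posture_matrix()` and `normalize_cohort()` —
the same path the simulated trials take.

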