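---
title: "Methods: lesion-aware structure-function connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-aware structure-function connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfc)
```

## The scientific question

Resting-state fMRI functional connectivity (FC) is widely assumed to be
carried by white-matter structural connections, but testing that assumption
requires structural variation. Focal lesions (stroke) provide it: each
patient loses a different subset of tracts, so across a cohort one can ask,
edge by edge, whether losing a structural connection shifts the functional
coupling it supports — and which *communication model* (direct edges,
shortest-path routing, or diffusion over multi-edge paths) best predicts
where those shifts appear. `lesionfc` implements this analysis end to end
and ships a synthetic-cohort generator so the whole pipeline is executable
and testable without patient data.

## Virtual tractography

Patient diffusion imaging is typically unavailable or unreliable around a
lesion, so subject-specific connectomes are built *virtually*: a template
set of streamlines (healthy-subject tractography in a common space, each
streamline resampled to a 100-point cubic spline) is intersected with the
patient's binary lesion mask, and every streamline with at least one of its
100 points inside a lesion voxel is removed. Points map to voxels by
nearest-voxel rounding under the volume affine; the containment rule is
deliberately point-based (not segment-voxelized) and is pinned against a
brute-force per-point oracle in the tests.

Edge weights follow the length-debiased sum `W_ij = sum_s 1/l_s`, where
`l_s` is the polyline arc length of the resampled streamline — tractography
over-produces long streamlines, and down-weighting by length compensates.
`raw_count` and `roi_size_normalized` variants are kept behind a `mode`
flag because the communication analysis is re-run under them. Two further
conventions the data do not dictate: interhemispheric streamlines are
restricted to homologous ROI pairs at template construction (crossing
fibers between non-mirror regions are dominated by tracking noise), and a
*high damage* label for subject k on edge (i,j) means k's weight is
*strictly* below the across-subject median for that edge, ties counting as
low damage; with even cohorts the median is the usual midpoint of central
order statistics. Edges are modeled only when at least `min_subjects`
(default 3) subjects show high damage — below that the damage GLM has no
usable contrast.

## Partial correlation with a structural prior

For Gaussian ROI series with covariance Θ, zeros in the precision
Φ = Θ⁻¹ encode conditional independence; the partial correlation
`PC_xy = −Φ_xy / sqrt(Φ_xx Φ_yy)` measures coupling between x and y with
all other ROIs held fixed, which is exactly the single-edge dependence the
structural question concerns. Direct inversion of a 114-ROI covariance from
~172 volumes is hopeless, so the support of Φ is estimated by an *adaptive
graphical lasso*: the usual L1-penalized Gaussian likelihood, but with a
two-level penalty keyed to the binarized SC — `lambda_sc` on ROI pairs with
a structural edge, `lambda_non_sc` elsewhere, diagonal unpenalized. Only
the *pattern* of the SC is used: structural weight does not map onto
precision magnitude across individuals, so weight-proportional penalties
are deliberately avoided.

The solver is block coordinate descent over columns of the working
covariance with an elementwise penalty matrix (RcppArmadillo), terminated
by the duality gap `tr(ΘΦ) − p + Σ λ_jk |Φ_jk| ≤ tol` (default 1e-6,
max 500 sweeps; non-convergence is an error carrying the gap, never a
silent return). The selected support is then *refit* without shrinkage:
maximize the Gaussian likelihood constrained to the support, against the
ridged covariance `Θ + δI` with `δ = 0.001 × max(upper triangle of Θ)` to
guard rank deficiency. The refit uses the classical per-column regression
algorithm; at convergence the fitted covariance matches `Θ + δI` exactly on
the support and diagonal (asserted to 1e-6 relative in tests). Signed PC
output uses the conventional negative sign; the damage analysis consumes
`|PC|`, which is invariant to that choice.

Penalty selection is by split-half cross-validation: the series is split
into contiguous first/second halves (fMRI autocorrelation makes interleaved
splits leak information across folds), each half is fitted
(lasso → refit), and each half's precision is scored against the *other*
half's covariance,
`Dev = 0.5(−log det Φ̃₁ + tr(Θ₂Φ̃₁) − log det Φ̃₂ + tr(Θ₁Φ̃₂))`,
averaged across subjects per grid point (the across-subject sd is what the
error bars on `autoplot(cv_result)` show). The default grid is 16
log-spaced values in [0.01, 0.5] with `lambda_non_sc` fixed at 0.2, and the
plain graphical lasso is evaluated over the same grid as the
uniform-prior baseline. All FC-fitting paths standardize each ROI series to
unit variance first: partial correlation is scale-invariant, and only on
the correlation scale are penalties like 0.125/0.2 meaningful across
datasets.

## Edge-wise damage models

Transformed FC values `atanh(|r|)` are positive and right-skewed, so each
edge's across-subject (or across-observation) values are modeled as gamma
with a log link: `ln E(y) = β₀ + β₁·damage`. β₁ is the log ratio of mean
transformed FC in high- vs low-damage groups; its Wald test uses the
Pearson-estimated dispersion. Partial correlations receive a constant 1e-4
offset (exact zeros are produced by the lasso support and the gamma density
is undefined at 0); for plain correlations the offset is applied only to
exact zeros. The IRLS iteration cap is raised to 200 because responses
mixing the 1e-4 offset with order-1 values converge slowly; edges whose fit
still fails, or whose damage indicator is constant, are excluded from the
FDR family and logged with a reason. Multiplicity is handled by
Benjamini–Hochberg at α = 0.05 (the field default when only "FDR" is
stated), cross-checked in tests against a brute-force step-up enumeration.

At the voxel level, each streamline contributes the Pearson correlation of
the BOLD series at its two endpoint voxels (sFC), per subject, with the
streamline's disconnection status as the damage indicator — each
(streamline, subject) pair is one observation, with no within-subject
random effect. Endpoints falling outside the brain mask are *rejected*
(recorded, not errored): no BOLD signal exists there. Pairs whose endpoints
round to the same voxel would contribute r = 1 identically and are excluded
and flagged; exact duplicate voxel pairs within an edge and subject are
deduplicated so each unique termination-point pair counts once.

## Communication models

From the *undamaged* SC: mean first passage time (MFPT) of the random walk
whose step probabilities are proportional to edge weights, computed exactly
via the fundamental matrix `Z = (I − P + 1π')⁻¹`,
`MFPT(a,b) = (Z_bb − Z_ab)/π_b` (Monte-Carlo walkers serve as the test
oracle only); edge betweenness centrality with path lengths `1/weight`
(stronger = shorter; the reciprocal is the standard weight-to-length
inversion), fractional tie-splitting, pinned against exhaustive path
enumeration on all connected 5-node graphs; and the raw weight. MFPT is
symmetrized as `(M + M')/2` *before* z-scoring — the order is ambiguous in
principle but irrelevant for symmetric inputs — and all three predictors
are standardized over the eligible-edge set actually entering the
regression. After rank-sum screening, the binary modulated/unmodulated edge
labels are regressed on the three standardized predictors by logistic
regression; perfect separation falls back to a small-ridge IRLS fit,
flagged, with no p-values fabricated. Lower MFPT means a random walker
reaches the other ROI faster, i.e. higher expected FC, so a *negative*
MFPT coefficient is the diffusion-model signature.

## The synthetic cohort: what it emulates, and what it does not

The generator plants exactly the statistical structure the estimators
assume, with defaults mirroring the target study design: 20 subjects, 172
usable volumes, a homologue-paired parcellation (20 ROIs by default, up to
114) on a 3 mm isotropic grid, heterogeneous spherical lesions confined to
the left hemisphere with radii 5–18 mm (volumes up to ~25 cm³, matching the
published cohort's range), and 2–5 streamlines per SC edge with SC density
0.35 within hemisphere plus a connectivity backbone.

The ground-truth precision is the simplest GGM faithful to the SC-support
assumption: off-diagonals `−c·1[SC edge]` with `c = 0.3`, diagonal = row
sum of absolute off-diagonals + 1 (strict diagonal dominance ⇒ positive
definite; an internal eigenvalue check errors rather than proceeding on a
non-PD construction). Damage acts *multiplicatively*: per subject, the
coupling on edge (i,j) is scaled by `1 − a·f_ij` where `f_ij` is the
fraction of that edge's streamlines the lesion disconnects and `a` is
`coupling_attenuation` (0 = null cohort, i.e. lesions exist but have no
functional consequence). Endpoint-voxel series are the ROI signal plus a
per-streamline shared component (weight 0.6, scaled by `1 − a` when
disconnected) plus independent noise (sd 0.4). Damage never deletes
observations, so group sizes stay balanced.

What this does **not** emulate: hemodynamics, scanner noise and motion,
spatial autocorrelation, global/common-input signal, and preprocessing
effects. Two consequences matter for interpreting green tests. First, the
planted partial correlations, `c/sqrt(d_i d_j) ≈ 0.10–0.15` under the
diagonal-dominant construction, are weak relative to real fMRI: with 172
volumes they sit near the graphical lasso's detection threshold, so the
cross-validation advantage of the SC prior over the uniform prior is
present but small (it is asserted on replicate-averaged deviance curves),
and ROI-level damage detection is noisy. Second, real marginal correlations
are dominated by common input and indirect paths, which is what makes them
*insensitive* to single-edge damage in patient data; the generator has no
common-input component, so marginal correlation is more damage-sensitive
here than in real recordings, and the clean empirical ordering "streamline
FC ≫ partial correlation > correlation" compresses at the ROI level. What
passing tests do show: every estimator recovers its planted quantity
(support F1, log-mean-ratio, communication coefficients) at the stated
sizes, error control holds (GLM type-I, FDR, rank-sum calibration), and the
voxel-level sFC response detects planted disconnection vastly better than
either ROI-level response.

## Numerical choices and degenerate inputs

* Covariance uses the 1/n (maximum-likelihood) normalization consistent
  with the deviance formula; constant ROI series are an error naming the
  ROI.
* The lasso solver's inner coordinate descent runs to 1e-10; the outer loop
  certifies a duality gap ≤ 1e-6. The penalized objective per sweep is
  logged and is non-increasing (asserted in tests).
* Correlations at |r| ≥ 1 are a domain error for the Fisher transform;
  constant endpoint series are an undefined-correlation rejection.
* The tests and acceptance script run at deliberately desk-scale problem
  sizes — p = 20 ROIs, 10 cohort replicates for the cross-validation and
  power comparisons, n = 5000 volumes for consistency checks, 1000
  replicates for GLM calibration — chosen so the full suite completes in a
  few minutes while each assertion retains statistical teeth.
* Seeds: a cohort is a pure function of its `cohort_config` (including
  `rng_seed`); the acceptance script derives per-stage seeds from one
  `--seed` so every number it writes is reproducible.

## Known limitations

Streamline intersection uses the 100 sample points, not voxelized segments,
so a streamline grazing a lesion between samples can be missed (the
template's own resampling makes this rare at 3 mm). The homologue
restriction is applied at template construction; applying it after lesion
intersection would give identical results. The pipeline assumes
co-registered inputs and performs no registration; subcortical ROIs are out
of scope; and the gamma GLMs treat (streamline, subject) observations as
independent — a within-subject random effect is a possible extension but
is deliberately not fitted, matching the plain-GLM design the analysis
follows.
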