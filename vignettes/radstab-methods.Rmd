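---
title: "radstab: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radstab: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radstab)
```

This vignette records how the pipeline is defined, which choices were
genuinely open, and what its green tests do and do not establish. It is
the companion to the README's worked example; it states no empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## The study design being modelled

Two co-aligned acquisitions of the same lesion — a conventional reference
sequence and a fast variant — are compared feature by feature across
subjects. Features are extracted per (subject, sequence, lesion class,
mask kind) task. Masks come in two kinds per pair: each sequence's own
*whole* mask, and the voxelwise *intersection* of the reference and fast
masks, transferred to both images. For a group with two fast sequences
this yields 3 whole + 4 intersection mask roles, 14 over two groups. With
one fast sequence the same rule gives 2 + 2 = 4 roles.

Agreement is Lin's concordance correlation coefficient with n-denominator
moments,

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

a feature is *stable* iff $\rho_c > 0.85$ (strict inequality), and stable
proportions of two fast sequences are compared with McNemar's test on the
paired indicators.

## The 595-feature catalog

The catalog is fixed and order-stable: 46 first-order + 61 texture
(5 second-order + 22 GLCM + 11 GLRLM + 5 LBP + 13 GLSZM + 5 NGTDM) + 488
wavelet (8 subbands × the same 61), total 595, asserted at construction.
Two membership questions had no recoverable ground truth and are resolved
as package conventions:

* **First-order membership.** Only the cardinality (46) and the
  histogram-analysis character of the family are fixed externally. The
  package documents an explicit 46-name list: 27 raw-intensity statistics
  (moments, quantiles, dispersion and energy measures) and 19 statistics
  of the discretized-level histogram (`hist_*`). The exact membership is
  a convention; reproducing any external per-feature table is explicitly
  not a goal.
* **"Second order" vs GLCM.** The taxonomy lists a 5-feature second-order
  family *separate from* the 22 GLCM features without naming its members.
  We implement 5 co-occurrence summaries disjoint from the 22-name GLCM
  list (dissimilarity, pair average, joint-maximum complement,
  difference/sum uniformity) and label them `secondorder_*` to flag the
  substitution.

## Discretization

Fixed bin *number* (Ng = 32 by default, `discretization$ng`), not fixed
bin width: the two sequences of a pair sit on different intensity scales
(different TR/TE), and fixed-bin-number is invariant under positive
affine rescaling — a property the test suite checks. Bin edges are
computed from in-mask intensities only. A constant ROI maps to level 1
everywhere and carries a degenerate flag so downstream features report
`NA` ("undefined") rather than arbitrary numbers; undefined values are
never silently zero and are dropped pairwise per feature by the CCC stage
with the effective n recorded.

## Texture matrices: 2D, pooled

All texture matrices (GLCM, GLRLM, GLSZM, NGTDM, LBP) are built per slice
with in-plane neighbourhoods and pooled over slices. Rationale: the
emulated protocols use 5 mm slices with 2 mm gaps, so through-plane
neighbourhoods are physically inhomogeneous (7 mm vs ~1 mm in-plane).
GLCM uses distance 1, the four in-plane directions, symmetrization, and
*count pooling* before normalization (not per-direction feature
averaging) — the more stable choice for small ROIs. Runs (GLRLM) are
maximal constant-level in-mask segments along the four directions;
out-of-mask voxels break runs. Zones (GLSZM) are in-plane 8-connected
components. NGTDM uses the in-mask 8-neighbour mean; its coarseness is
capped at 10^6 in the degenerate all-constant case. LBP is the P=8, R=1
rotation-invariant uniform code computed on *raw* intensities (not
levels) for in-mask voxels with a complete in-plane neighbourhood, with
ties (neighbour ≥ centre) mapping to a set bit.

Every matrix builder is checked against an independently written
brute-force enumerator (plain voxel loops) on 100 random 6×6×2 ROIs.

## Wavelet subbands

The "× 8" wavelet block is realized as a **two-level undecimated 2D**
separable transform per slice (Haar by default, `wavelet$family`):
level-1 LL/LH/HL/HH plus level-2 LL2/LH2/HL2/HH2 applied to the level-1
LL band, with half-sample symmetric boundaries. A single-level 3D
transform would also give 8 subbands, but 3D filtering across gapped
5 mm slices is physically dubious, and the undecimated 2D choice keeps
every subband on the source grid so the unmodified ROI mask applies. Each
subband is re-discretized within the mask (same Ng) before the 61 texture
features are computed. Undecimated filtering commutes with in-plane
translation, which the suite verifies end-to-end on interior lesions.

## Lin's CCC: edge cases

`lin_ccc` drops incomplete pairs and requires ≥ 3 complete pairs. A zero
denominator forces both lists to be constant *and equal* (zero variances
and equal means), i.e. the measurements agree exactly; the package
reports ρ_c = 1 there rather than 0/0. This matters because a few catalog
features are constant by construction across subjects (e.g. the
discretized-level range is Ng − 1 for every non-degenerate ROI), and the
identity-degradation null experiment — same volume on both arms — must
classify every feature as perfectly concordant.

Stability is strict (`> 0.85`); an undefined CCC is never stable. The
stable proportion uses the full 595 as denominator (undefined counts as
unstable), matching an "x/595" presentation; the per-feature effective n
is reported alongside.

## Median CCC confidence intervals and "overall" rows

The CI method for the median CCC was not externally specified; we use a
seeded percentile bootstrap over features (2000 replicates by default,
`stability$bootstrap_reps` / `bootstrap_seed`). The "overall" lesion
stratum is interpreted as the pooled acute + chronic subject-lesion set;
this definition is isolated in one place (`run_stability_study`) so it
can be changed without touching anything else.

## McNemar's test

Discordant counts b (stable under A only) and c (stable under B only)
drive the test. At b + c ≥ 25 (`stability$mcnemar_exact_cutoff`) the
continuity-corrected χ² statistic \((|b-c|-1)^2/(b+c)\) with 1 df is
used; below that, the exact two-sided binomial test (doubling the smaller
tail, capped at 1). b + c = 0 returns p = 1 ("degenerate"). The exact
branch is verified against full outcome enumeration for every b + c ≤ 12.

## The synthetic cohort: what it emulates, and what it does not

Phantoms are textured hyperintense lesions: background 100 plus a smooth
Gaussian-correlated field (amplitude 5% of lesion contrast), lesion
voxels add a contrast of 60 plus a correlated texture field (amplitude
12, correlation length 6 mm, radius 10–13 mm). These magnitudes are
simulator conventions chosen once to give a clearly textured,
non-degenerate lesion against a darker background; no external intensity
statistics were available to calibrate them.

Acquisition profiles apply, in order: in-plane Gaussian blur
(`blur_fwhm`), linear down-sampling to the acquisition matrix (physical
field of view preserved), additive Gaussian noise with
sd = `noise_sigma` × lesion-background contrast, and nearest-neighbour
mask transfer with seeded one-voxel boundary erosion/dilation
(`mask_jitter`) so whole and intersection masks genuinely differ. The
four default profiles carry the protocol-table matrices (conventional
256×218, EPI 128×128, ETL 192×192, TR 256×256); noise is drawn from the
documented grid {0, 0.05, 0.15} with ETL noisiest, blur from {0, 1.5 mm}.
The `scale` argument shrinks all matrices proportionally (default demo
scale 0.25) so desk-scale runs complete in seconds per task.

Deliberate non-goals: no Bloch-equation signal simulation, no k-space
undersampling artifacts, no EPI geometric distortion, no inter-sequence
contrast change (TR/TE affect only the emulated matrix/noise/blur, not
tissue contrast), and no per-sequence manual re-segmentation (replaced by
seeded boundary jitter). Consequently a green end-to-end test establishes
that the *pipeline* is correct and directionally sensitive (more noise ⇒
lower CCC), **not** that any particular fast sequence is clinically
preferable — at quarter scale, for instance, the EPI-like profile's
coarse matrix outweighs the ETL-like profile's heavier noise, inverting
the ordering a clinical cohort showed. Cohort-level percentages from real
patients are cohort-dependent and are not an acceptance surface.

`simulate_feature_pairs` bypasses imaging entirely: it draws per-feature
pairs from a bivariate normal with equal means, unit variances and
correlation equal to the target CCC (with equal moments, Lin's
population coefficient equals the correlation), enabling
parameter-recovery tests of the estimator (±0.02 at n = 5000).

## Numerical and degenerate-input conventions

* Minimum ROI: 10 voxels; smaller masks are refused by extraction
  (texture matrices on fewer voxels are degenerate).
* Entropies are in bits (log2); 0·log 0 = 0.
* GLCM correlation is `NA` at zero marginal variance; IMC1/IMC2 at zero
  marginal entropy; NGTDM busyness at a single occupied level; NGTDM
  strength is 0 when all deviations vanish.
* Mask resampling across grids is nearest-neighbour (preserves
  binarity); intensity resampling is linear. How intersection masks were
  originally transferred across differing matrices is unknown —
  nearest-neighbour is this package's choice.
* All randomness flows from explicit seeds (cohort seed → per-subject,
  per-profile sub-seeds kept below 2^31); the full pipeline is a pure
  function of (config, seed) and reruns are byte-identical, which the
  suite asserts on written CSV output.

## Known limitations

* The per-feature membership of the first-order and second-order families
  is a documented convention (see above), so per-feature comparisons with
  other toolkits are only meaningful by name, not by position.
* Texture matrices are 2D-pooled; volumes with near-isotropic voxels
  might prefer 3D neighbourhoods, which this package does not implement.
* `yaml`/JSON configuration covers the documented keys only; unknown keys
  are merged but unused.
* The CLI is single-process; desk-scale cohorts need no parallelism.
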