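---
title: "Quantitative CT texture and histogram analysis of neoadjuvant response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT texture and histogram analysis of neoadjuvant response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoresponse)
```

# The problem

After neoadjuvant therapy for locally advanced lung adenocarcinoma, the
reference standard of response is pathologic: the fraction of necrosis in
the resected specimen (more than 50% = responder, more than 90% =
near-complete responder; near-complete responders are a subset of
responders in every two-group analysis). Imaging-based surrogates are
needed weeks earlier, but size-based criteria miss responses to
growth-inhibiting agents (EGFR-TKIs), where tumor tissue devitalizes
without early shrinkage. This package quantifies, per patient, how seven
CT-derived features change between the baseline and follow-up scan, and
asks — separately per treatment arm, since the arms are never pooled —
which features' percent changes separate pathologic responders from
nonresponders.

# Feature definitions and conventions

All features are computed from the masked voxel sample of one scan: the
attenuation values (HU) of all mask-foreground voxels, their 1-based
(x, y, z) grid indices, and the unit voxel volume in mm³. Volume and mask
must be voxel-aligned; spacings may differ by at most 1e-4 mm (format
rounding), and no resampling is ever performed.

**First-order.** Volume is voxel count × unit volume (cm³). Density uses
the linear attenuation convention ρ = 1 + mean(HU)/1000 g/cm³, under which
water (0 HU) has unit density and a solid tumor at ~130 HU has
ρ ≈ 1.13 g/cm³; a mean below −1000 HU would be non-physical and errors.
Mass = volume × density is an exact identity, tested to 1e-12 relative.
Skewness and kurtosis are population standardized moments of the raw HU
histogram (g₁ = m₃/m₂^{3/2}; kurtosis m₄/m₂², non-excess, so a Gaussian
gives 3). Sample-corrected and excess variants exist
(`type = "sample"`, `excess = TRUE`) because it is not knowable which
convention a given clinical software used; the convention in force is
echoed into every report. Histogram features use raw HU values — the
16-level resampling below applies to texture only. Zero-variance samples
make skewness/kurtosis undefined: they return `NA` flagged with
`undefined = TRUE` rather than crashing, and reports carry the row marked
undefined rather than dropping it.

**Texture.** ROI voxels are resampled to L = 16 gray levels by uniform
binning over the ROI's own (min, max):
level = min(L, ⌊L·(v − min)/(max − min)⌋ + 1), with a flat ROI mapping to
level 1. Per-scan min–max binning normalizes intensity across subjects; a
fixed HU window is available (`huRange`) for studies that prefer it, and
this open choice defaults to per-scan. Zones are maximal connected
components of equal level; the default neighborhood is the full
26-connectivity in 3-D (the usual choice for size-zone analysis), with
6-connectivity and per-slice 8-connectivity ("8-2d") selectable. Zones
live on the voxel lattice regardless of physical spacing — anisotropic
voxels (e.g. 1×1×3 mm) are not resampled, so zone sizes are voxel counts,
not volumes. The GLSZM M(m, n) counts zones of level m and size n; its
validity method enforces Σ n·M(m,n) = foreground voxel count on every
instance. Intensity variability IV = Σₘ(Σₙ M(m,n))² and size-zone
variability SZV = Σₙ(Σₘ M(m,n))² are the unnormalized size-zone sums —
low IV means a gray-level-homogeneous tumor, low SZV uniformly sized
zones, and a uniform ROI gives exactly IV = SZV = 1. Zone-count-normalized
variants are available behind `normalized = TRUE` under the same names,
never silently substituted.

# Statistical procedure

Percent change is 100·(post − pre)/|pre|. The absolute-value denominator
is deliberate: baseline skewness of solid tumors is typically negative,
and with a signed denominator a decrease of a negative quantity would
report as positive. With |pre|, a decrease is always negative. A zero
baseline leaves the change undefined (`NA`), and the variable is reported
as undefined rather than omitted.

Group comparisons use the two-sided Mann–Whitney test. With both groups of
size ≤ 12 (configurable) the exact null distribution is used — the
closed-form count distribution when there are no ties, or full enumeration
of all group assignments when there are (capped at ~3·10⁶ tables, above
which the approximate path is taken); otherwise a normal approximation
with tie correction and continuity correction. The two-sided p is the null
probability of a U at least as far from mn/2 as observed. The statistic
and which path ran are recorded in every report row. Categorical contrasts
use the two-sided Fisher exact test (sum of hypergeometric probabilities
not exceeding that of the observed table).

Variables whose Mann–Whitney p between responders and nonresponders is
below 0.50 (strict inequality; configurable) enter the logistic model
simultaneously. Model reduction is pure backward elimination by
likelihood-ratio deletion tests: at each step the variable with the
largest deletion p is removed if that p is ≥ 0.10, until none qualifies.
Ties in deletion p are broken alphabetically, so the final model never
depends on the order variables were supplied. Aliased or constant
covariates contribute zero likelihood and are removed with p = 1. A
forward/backward hybrid was considered and rejected in favor of a single
well-tested path: the procedure's description in the clinical literature
mixes entry and removal language, and pure backward-LR with all screened
variables entering is the reading that makes the 0.50 screen meaningful.
Retained variables are reported as odds ratios per unit percent change
with Wald 95% CIs and Wald p. Complete or quasi-complete separation —
common at n ≈ 23–28 with strong effects — is detected from fitted
probabilities numerically at 0/1 and flagged in the report; LR-based
elimination remains well behaved under separation, but the Wald intervals
are then unreliable and are marked so.

ROC analysis reports the empirical AUC (pairwise concordance, ties counted
half) and the cutoff maximizing Youden's J = sensitivity + specificity − 1.
Candidate cutoffs are midpoints between adjacent observed scores (plus
open ends); ties in J break toward higher sensitivity. For features that
decrease under response the rule reads "less than c predicts response";
direction is chosen from group medians when not fixed by the caller. The
pipeline computes ROC both for each retained variable's raw percent change
and for the fitted model's linear predictor, since it is not knowable
which scale a given clinical analysis used.

# The synthetic cohort generator

No patient images ship with the package, so `generateCohort()` builds the
study design synthetically: two arms (TKI n = 23 with 10 responders, 4 of
them near-complete; CCRT n = 28 with 12 responders, 7 near-complete),
paired pre/post scans, and a pathology-side necrosis fraction drawn
uniformly within the label-consistent interval (it is a label carrier, not
an imaging quantity).

Each phantom is an ellipsoid on a 1×1×3 mm grid (thin-slice in-plane,
thicker axial spacing, as in routine chest CT) against a lung-like −800 HU
background. Baseline volumes are log-normal around ~19–25 cm³ (clamped to
5–80 cm³) and mean attenuation ~130 ± 25 HU, so default cohorts sit at the
scale of real solid adenocarcinomas (mean volume 15–40 cm³, density
0.9–1.4 g/cm³ — asserted by test). Internal texture is a Gaussian random
field (white noise smoothed by an FFT Gaussian kernel with correlation
length ~3.5 mm, marginal SD ~45 HU) plus white voxel noise (10 HU) plus
*necrotic pockets*: the top ~1–4% of a second, smoother field (6 mm) is
shifted down by ~330 HU. Small deep pockets produce the negatively skewed,
leptokurtic baseline histograms characteristic of enhancing tumors with
focal necrosis; every phantom is a pure function of its parameters and
seed.

Treatment effects have four knobs: `volumeScale` (radii scale by its cube
root; the post mask is a rescaled ellipsoid, not a deformation — no
registration machinery), `huShift`, `pocketDelta` (necrosis spreading),
and `homogenization`. Homogenization multiplies macroscopic contrast
(texture SD, pocket depth) by the factor, divides the correlation length
by it, and multiplies voxel noise by its square. The quadratic noise term
is the load-bearing choice: per-scan min–max quantization cancels any
joint contrast scaling, and zone counts are in practice governed by the
noise-to-bin-width ratio (each occupied level percolates into one giant
zone; the remaining zones are noise-generated fragments). Scaling noise
by the square makes that ratio fall linearly in the factor, so expected
IV and SZV decrease monotonically as homogenization strengthens — the
property the texture features are meant to measure. Factors up to 2 are
allowed because real nonresponder distributions include growing and
roughening tumors.

Default effect distributions are *synthetic calibration*, not estimates:
they were chosen once to reproduce the qualitative two-arm structure and
the signs of the dominant published effects, and then frozen. TKI arm:
responders volumeScale ~N(0.49, 0.20), homogenization ~N(0.55, 0.12);
nonresponders ~N(0.58, 0.20) and ~N(1.05, 0.15) — both groups shrink
comparably (so size does not discriminate), texture separates them. CCRT
arm: responders volumeScale ~N(0.45, 0.30) with necrosis spread
pocketDelta ~N(0.20, 0.06) (strong kurtosis/skewness change) and mild
heterogenization ~N(1.35, 0.25), which matches the sign of published
texture increases under chemoradiation and offsets the volume-shrink
effect on zone counts, so texture does not discriminate in that arm;
nonresponders ~N(0.86, 0.35). Attenuation shifts are wide
(SD ~100 HU) so density separates weakly everywhere. One caveat the
generator does not hide: published cohort-mean percent changes of skewness
and kurtosis cannot be realized jointly by any single histogram
deformation (kurtosis ≥ skewness² + 1 constrains the implied
post-treatment pair), because they are means of per-patient ratios; the
generator therefore targets the discriminating structure and dominant
signs, not the joint means — under its CCRT-responder effect, skewness
moves toward zero while kurtosis collapses.

What the phantoms do **not** emulate: real lung anatomy, ground-glass
components, cavitation, contrast-phase differences, scanner/dose noise
models, segmentation variability, or registration error. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers a known
generative structure at realistic n — not that the clinical effect sizes
are reproduced.

# Numerical choices and degenerate inputs

- Spacing comparisons use a 1e-4 mm tolerance; round-trip spacing is
  preserved to ≤ 1e-6 mm.
- Quantization at max = min maps all voxels to level 1 (degenerate but
  defined); IV = SZV = 1 follows.
- Masks with values {0, v} load by > 0 thresholding with a warning; three
  or more labels require an explicit selector.
- Mann–Whitney enumeration uses a 1e-9 slack when comparing deviations of
  the (half-integer) U statistic; Fisher delegates to `stats::fisher.test`
  whose two-sided rule is exactly the hypergeometric sum.
- Backward elimination's alphabetical tie-break makes results
  order-invariant; separation is flagged, never silently accepted.
- ROC cutoff ties in J break toward higher sensitivity; cutoffs are
  midpoints, so reported rules never sit on an observed score.
- Everything downstream of a seed is deterministic: cohorts, manifests,
  feature tables and reports are byte-identical across reruns with the
  same master seed (asserted by test). Reports carry no timestamps for
  this reason; provenance is the config echo, seeds and package version.

# Problem sizes

The shipped tests and the acceptance script run at the package's chosen
desk scale: default cohorts of 51 patients on ~50×50×20-voxel grids;
25 replicate cohorts for the arm-structure study; 200 random 8×8×8 grids
against the flood-fill oracle; 200 logistic replicates at n = 60 for
parameter recovery; 10 homogenization levels × 20 phantoms for the
monotonicity study. The full suite runs in a few minutes on one CPU.

# Limitations

Masks are inputs: segmentation, registration and DICOM assembly are out of
scope. The GLSZM definitions are the unnormalized size-zone sums; studies
using normalized variants should request them explicitly. The logistic
models at n ≈ 23–28 with up to seven candidate variables frequently
separate — the package reports this honestly rather than regularizing,
because the modelled procedure did not regularize. Percent-change analyses
depend on the kurtosis convention only through the |pre| denominator
choice; both are echoed into every report header precisely so that
downstream comparisons cannot be convention-blind.
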