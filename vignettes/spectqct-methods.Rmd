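---
title: "Methods: integrated SPECT and qCT analysis of lung ventilation heterogeneity"
author: "spectqct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated SPECT and qCT analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

COPD damages the lung in two distinguishable ways: functional small
airway disease (fSAD; small airways narrow and trap gas without
destroying parenchyma) and emphysema (parenchymal destruction). Both
disturb how inhaled air distributes, which SPECT ventilation imaging
sees directly as a heterogeneous tracer distribution. This package
implements the quantitative layer connecting the two modalities:

* **qCT biomarkers** from a registered inspiration/expiration CT pair:
  the parametric response map (PRM) that classifies each lung voxel as
  Normal, fSAD or emphysema from its Hounsfield-unit (HU) pair; the
  Jacobian determinant *J* of the deformation (local volume-change
  ratio, a ventilation surrogate); the anisotropic deformation index
  (ADI); tissue fraction; and lobar air-volume-change fractions
  including the upper-to-middle-plus-lower ratio.
* **SPECT statistics** on the tracer volume after alignment to the
  inspiration (TLC) CT domain: lobar tracer shares (TC%), whole-lung
  heterogeneity (CV\_Total = SD/mean of voxel tracer concentration),
  and the standardized maximum (TC\_Max, hot-spot magnitude).
* **Registration**: mutual-information affine alignment of SPECT to
  CT, and mass-preserving deformable registration of the deflated to
  the inflated CT.
* **Statistics**: Pearson correlation maps with effect-size bands,
  exploratory factor analysis (parallel analysis, principal-component
  extraction, Varimax), and two-wave cross-lagged panel analysis.
* A **ground-truth thorax phantom** generator, and the packaged
  per-subject tables of an eight-subject, three-visit COPD cohort from
  which every published summary statistic and correlation is
  recomputed.

# Voxel models and conventions

**HU mixture model.** A voxel is an air/tissue mixture:
$\beta_{tissue} = (HU + 1000)/1000$, clamped to $[0,1]$. Pure air is
$-1000$ HU, soft tissue $0$ HU. This makes tissue fraction invertible
from HU, which both the phantom generator and the mass-preserving
registration rely on.

**PRM thresholds.** A lung voxel is emphysema when inspiration HU
$< -950$ *and* warped-expiration HU $< -856$; fSAD (gas trapping) when
only the expiration criterion holds; Normal otherwise. The thresholds
are the established PRM values and are exposed as arguments
(`prmClassify(..., thrInsp, thrExp)`).

**Coordinates.** World coordinates are in mm,
`world = origin + (index - 1) * spacing`, volumes 1-indexed.
Displacement fields live on the fixed grid in pull-back convention: a
field $u$ maps fixed points $x$ to moving points $x + u(x)$, so
warping never requires field inversion.

**Air-volume change.** Per voxel,
$\Delta V_{air} = v\,[(1-\beta_{insp}) - J\,(1-\beta_{exp}^{warped})]$
(volume $v$, warped expiration tissue fraction on the inspiration
grid). Under exact tissue-mass preservation this reduces to
$v\,(1-J)$, which `lobarVentilation()` uses when the CT pair is not
supplied; both routes agree on phantoms and the agreement is tested.

**Summary rows.** `summarizeTable()` defaults to the population SD
(`ddof = 0`): the packaged study tables print Mean ± SD rows in that
convention, and the reproduction tests check the printed cells to
±0.01. The sample SD (`ddof = 1`) is one argument away.

# Registration

**Affine, by mutual information.** SPECT and CT are different
modalities, so alignment maximizes the mutual information of the joint
intensity histogram over rigid (default) or full affine parameters,
multi-resolution with a coarse translation grid search for capture
range, then Nelder-Mead refinement. The histogram is evaluated over
the fixed-image lung mask dilated by about two voxels. The default is
48 histogram bins: coarser histograms flatten and bias the MI surface
for count-valued tracer images, and the sub-voxel recovery contract
(checked by the test suite and reported by the acceptance script) is
what fixed this default. `bins` remains an argument.

**Deformable, mass-preserving.** The deflated-to-inflated field is
estimated by a multi-resolution, Gaussian-regularized demons-style
iteration whose residual is the *tissue-volume* mismatch
$r = \beta_{insp}(x) - J(x)\,\beta_{exp}(x+u(x))$ — the $J$ factor
makes the objective mass-preserving rather than intensity-preserving,
which matters because the same tissue is denser at expiration. The
per-iteration step is capped at one voxel (larger caps produce a
small but systematic over-compression bias), updates are smoothed with
a fluid-like Gaussian (σ = 1 voxel) and the accumulated field with a
diffusion-like Gaussian (σ = 0.75 voxel), over strides 4/2/1 with
80/60/40 iterations. The contract — and what the tests check — is
recovery accuracy against known fields (mean endpoint error < 2 mm at
the phantom's default 6 mm peak displacement) and tissue-volume
conservation through the recovered warp (within 2%), not algorithmic
identity with any particular published parameterization.

**Deformation metrics.** $J = \det(I + \nabla u)$ by central
differences. ADI comes from the principal stretches
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the right stretch tensor
$U = \sqrt{F^\top F}$ (closed-form symmetric eigenvalues):
$ADI = \sqrt{((\lambda_1-\lambda_2)/\lambda_2)^2 +
((\lambda_2-\lambda_3)/\lambda_3)^2}$, zero for locally isotropic
deformation, 1 for a uniaxial stretch of ratio (2,1,1).

# SPECT statistics

All three statistics are computed on the tracer volume after
resampling into the TLC CT domain (affine to the deflated CT, then the
deformable field to TLC), within the lung mask, and all are invariant
to global count rescaling — absorbing differences in inhaled tracer
amount. TC\_Max is standardized as max/mean. The hot-spot statistic
has no single canonical definition; max/mean is dimensionless,
scale-invariant, equals 1 for a homogeneous field, and matches the
magnitude range of the packaged study tables. Alternatives
(99.9th-percentile/mean, max/median) are selectable.

# The phantom generator

The phantom emulates the statistical structure the analysis assumes,
at desk scale:

* **Geometry.** Two ellipsoidal lungs split into five lobes by planes,
  in a 64³ grid at 2 mm CT spacing (~13 cm lung height — a half-scale
  thorax; at the native 0.5–0.7 mm scanner resolution a whole lung
  needs a ~400³ grid, which buys nothing for testing the analysis).
  SPECT companion at 3.9 mm. The analysis lobe map sits a few voxels
  inside the pleura, as real lung segmentations do; HU is generated
  over the full lung so pleural partial-volume voxels exist in the
  images but not in the mask.
* **Disease.** fSAD and emphysema are seeded as spherical blobs to the
  requested voxel fractions (defaults 12% and 13%, the cohort means).
  Blob seeding is nested under a fixed seed, so growing a fraction
  extends rather than rearranges the disease.
* **Deformation.** Deflation is a uniform contraction toward the
  thorax centre (healthy $J = (1-s_0)^3$ exactly) plus a compact
  volume-source field at each diseased blob: inside a blob the source
  gradient is isotropic, fixing the blob's $J$ exactly; outside it
  decays divergence-free as $1/r^2$. Diseased lung keeps 55% (fSAD)
  or ~78% (emphysema) of the healthy regional air-volume change —
  gas trapping without field folding ($J > 0$ everywhere). The default
  peak displacement is 6 mm: at the phantom's half scale that is a
  TLC-to-FRC-like breath-hold excursion, the pair the SPECT alignment
  chain uses.
* **HU sampling.** Tissue fractions are drawn per class *conditionally
  on the local discrete J*, so every lung voxel of the pair satisfies
  its seeded PRM class by construction; only interpolation at class
  boundaries can blur the classes. This is what makes ±2-point
  recovery of seeded fractions a meaningful end-to-end test of the
  warping and classification chain rather than of the generator.
* **Mass preservation.** The deflated volume is rendered by inverse
  warping (fixed-point iteration of $x = y - u(x)$) with
  $\beta_{exp} = \beta_{insp}/J$; total tissue volume of the pair
  agrees within 1% under the true warp.
* **SPECT.** Tracer concentration is proportional to regional
  air-volume change ($1-J$, clipped at 0) — a modeling choice; the
  aerosol literature supports proportionality to regional ventilation
  without fixing its functional form. Multiplicative Gaussian hot
  spots (σ = 2 SPECT voxels) sit at the centres of the first seeded
  fSAD blobs, mimicking focal deposition at the narrowed airway
  feeding a trapped region; their positions are therefore stable
  across a sweep of the seeded fraction. The field is extended outward
  by nearest-tissue padding before blurring to SPECT resolution
  (FWHM = one SPECT voxel) and resampling to the coarse grid — without
  the padding, the blur and resampling drag the lung rim toward zero
  and a partial-volume rim artifact dominates CV\_Total at this lung
  size in a way full-size lungs do not experience. A random rigid
  misalignment (±6 mm translation, ±3° in-plane rotation, recorded in
  the truth) exercises the affine registration, and Poisson counting
  noise (mean ~80 counts per lung voxel) is applied on the SPECT grid.

What the phantom does **not** emulate: airway trees, scanner physics
(scatter, beam hardening, attenuation), respiratory gating, body
habitus, and real-lung texture statistics. Passing recovery tests
therefore demonstrates the correctness of the computational chain
under the stated generative assumptions — not clinical performance on
patient data.

# Statistical layer

**Correlations.** Pearson r with a two-sided t test, and effect-size
bands on |r|: negligible (≤ 0.3), weak, moderate, strong (0.7, 0.9],
very strong (> 0.9). Correlation maps pool all subject-visit rows for
the cross-sectional mode — the packaged cohort has 22 such rows after
pairwise deletion of the two missing baseline SPECT scans — or
correlate between-visit changes for the longitudinal modes; cells with
|r| > 0.7 are highlighted, reflecting the effect-size-first reporting
appropriate for n of this size. The study tables print no direct
V2−V1 deltas for lung function; per-visit values are reconstructed
from baseline plus printed changes, making any between-visit contrast
derivable.

**EFA.** Parallel analysis retains the leading run of observed
correlation-matrix eigenvalues exceeding the 95th percentile of
eigenvalues from random normal data of identical shape (500
replicates by default). Extraction is principal components (loadings
are eigenvectors scaled by root eigenvalues) with Varimax rotation via
`stats::varimax` (Kaiser-normalized); key variables load above 0.6 in
absolute value. The seven-factor solution of the published analysis
derives from an external 799-smoker cohort and is not reproducible
from packaged data; the implementation is instead validated by factor
recovery on simulated block structures.

**Cross-lagged panel.** Six correlations over two waves: synchronous
r(x1,y1), r(x2,y2); stability r(x1,x2), r(y1,y2); and cross-lagged
*partial* correlations with the same-variable stability partialled out
— r(x1,y2 | y1) and r(y1,x2 | x1), conditioning on the one prior-wave
variable named in the panel diagram rather than on both. Tests are
one-sided (greater than zero), t with n−2 df for simple and n−3 for
partial correlations. Flags report failed synchronicity (a
non-significant synchronous correlation), non-stationarity (Fisher-z
difference of the synchronous correlations — an approximation, since
the two are dependent), and undefined partials when a stability
correlation is numerically perfect. The panel simulator
(`makePanelDataset`) generates the x-causes-y structure with the
reverse partial exactly zero in population, which is what makes its
power/type-I calibration checks sharp.

# Problem sizes and runtime choices

The test suite and the acceptance script run the phantom pipeline at
64³ voxels (≈17k lung voxels in the mask), registration at strides
4/2/1, simulation checks at 100 replicates of n = 200 panels and 20
factor-analysis datasets of 500 × 12. These sizes were chosen so the
full chain exercises every code path at comfortably interactive
runtimes while keeping all recovery contracts binding (none of the
tolerances is met trivially at these sizes).

# Known limitations

* The deformable registration is accurate to ~1 mm mean endpoint
  error at 6 mm peak displacements on phantom fields; much larger
  excursions (e.g. a full TLC-to-RV pair at this scale) degrade both
  endpoint error and mass conservation, and the PRM-through-
  registration contract is only guaranteed at the default conditions.
* PRM recovery degrades when combined disease burden exceeds roughly
  half the lung, as blob boundary shells (where trilinear
  interpolation mixes classes) begin to dominate.
* The cross-sectional pooling treats the three visits of one subject
  as independent rows, as the source analysis did; with n = 8 subjects
  the pooled correlations are descriptive effect sizes, not
  inferential estimates.
* Airway normalization implements the relative-deviation convention
  |measured − predicted| / predicted; the packaged normalized airway
  values are ingested as data and never recomputed from raw geometry.
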