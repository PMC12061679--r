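# spectqct

Integrated analysis of SPECT ventilation imaging and quantitative CT
(qCT) in chronic obstructive pulmonary disease (COPD), for imaging
scientists who want to relate structural lung damage to functional
ventilation heterogeneity.

COPD injures the lung through functional small airway disease (fSAD,
gas trapping) and emphysema. A registered inspiration/expiration CT
pair quantifies that structural damage voxel by voxel; a SPECT
ventilation scan shows how unevenly inhaled air actually distributes.
This package implements both sides and the statistics that connect
them:

* **qCT biomarkers** — parametric response mapping (each lung voxel is
  Normal, fSAD or emphysema from its HU pair under the −950/−856
  thresholds, giving fSAD% and Emph%), tissue fraction
  β = (HU+1000)/1000, the Jacobian determinant J of the
  deflation field (local volume change, a ventilation surrogate), the
  anisotropic deformation index ADI from the principal stretches, and
  lobar air-volume-change fractions ΔVairF with the upper-to-
  middle-plus-lower ratio.
* **SPECT statistics** on the tracer volume aligned to the TLC CT
  domain — lobar tracer shares (TC%), the whole-lung coefficient of
  variation CV_Total = SD/mean (heterogeneity), and the standardized
  maximum TC_Max = max/mean (hot-spot magnitude); all invariant to the
  amount of tracer inhaled.
* **Registration** — mutual-information affine alignment of SPECT to
  CT, and mass-preserving deformable registration minimizing the
  tissue-volume mismatch β_insp(x) − J(x)·β_exp(x+u(x)).
* **Statistics** — Pearson correlation maps with effect-size bands
  (|r| > 0.7 highlighted), exploratory factor analysis with parallel
  analysis and Varimax rotation, and two-wave cross-lagged panel
  analysis whose cross-lagged partial correlations (stability
  partialled out) indicate causal direction.
* **A ground-truth thorax phantom** (paired CT volumes, five-lobe
  label map, true deformation, SPECT with hot spots, Poisson noise and
  a recorded rigid misalignment) for end-to-end recovery testing, and
  the packaged per-subject tables of an eight-subject, three-visit
  COPD cohort.

## Worked example

```r
library(spectqct)

## published-table reproduction -------------------------------------
tab <- studyTables()$visits          # tidy subject-visit table (n = 24)
pearsonCor(tab$cv_total, tab$fsad_total)
#> Pearson r = 0.905 (n = 22, two-sided p = 7.605e-09) [very strong]

summarizeTable(tab, "fsad_total", "V0")
#>     mean       sd        n 
#> 12.08875 11.05897  8.00000

v1 <- tab[tab$visit == "V1", ]; v2 <- tab[tab$visit == "V2", ]
crossLaggedPanel(x1 = v1$fsad_total, x2 = v2$fsad_total,
                 y1 = v1$cv_total,  y2 = v2$cv_total)
#> Cross-lagged panel (n = 8, one-sided alpha = 0.05)
#>              r        p significant
#> sync1    0.930 4.00e-04        TRUE
#> sync2    0.945 2.03e-04        TRUE
#> stab_x   0.986 3.14e-06        TRUE
#> stab_y   0.975 1.91e-05        TRUE
#> cross_xy 0.786 1.81e-02        TRUE
#> cross_yx 0.141 3.81e-01       FALSE
```

The pooled ventilation-heterogeneity/fSAD correlation of 0.90 over the
22 complete subject-visit rows says that, cross-sectionally, gas
trapping and ventilation heterogeneity track each other almost
perfectly in this cohort. The cross-lagged panel reads: both
synchronous and both stability correlations are significantly positive
(the design's assumptions hold), fSAD at visit 1 predicts ventilation
heterogeneity at visit 2 beyond its stability (r = 0.79, p = 0.018),
while the reverse path does not (r = 0.14, p = 0.38) — small airway
disease drives the heterogeneity, not the other way round.

```r
## phantom pipeline --------------------------------------------------
rep <- runPipeline(phantomSpec(seed = 1))
rep$prm$fsadAbsError                      # 0.20 (percentage points)
rep$registration$meanEndpointError_mm     # 0.71
rep$spect$residualAlignmentError_voxels   # 0.59 (SPECT voxels)
rep$spect$rTcPercentVsTruth               # 0.95
```

A phantom subject with known disease, deformation and misalignment is
pushed through the whole chain; the seeded fSAD fraction is recovered
to 0.2 percentage points, the 6 mm deformation to 0.7 mm mean endpoint
error, the rigid SPECT offset to 0.6 SPECT voxels, and the lobar
tracer shares correlate 0.95 with the true lobar ventilation.

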