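# jmoct

Multi-contrast Jones-matrix optical coherence tomography (JM-OCT)
analysis for longitudinal small-animal imaging, built around a zebrafish
tail-musculature xenograft study design. The package is aimed at
biomedical-optics researchers who want to prototype, test and calibrate
the full JM-OCT analysis chain — contrast computation, segmentation,
longitudinal quantification, survival and vasculature statistics —
against synthetic volumes with known ground truth before (or alongside)
applying it to instrument data.

## What it computes

A JM-OCT system measures a complex 2 × 2 Jones matrix `J(z, x, y)` per
voxel, repeated `R` times per B-scan location. From these the package
derives the four standard contrast channels:

* **Scattering intensity** — the four absolute-squared matrix entries
  averaged per voxel and over repeats, in dB.
* **Local birefringence** — from the local Jones matrix
  `J_loc(z) = J(z + δz) · J(z)^{-1}`; the retardation is the eigenvalue
  phase split `δ = |arg λ₁ − arg λ₂|` wrapped to `[0, π]`, converted to a
  refractive-index difference `Δn = δ·λ_c / (4π·δz·Δz)` (depth pitch
  `Δz`, center wavelength `λ_c`), with an SNR-gated reliability channel.
  Ordered muscle is strongly birefringent; disorganized tumor tissue is
  not.
* **DOPU** (degree of polarization uniformity) — the norm of
  kernel-averaged normalized Stokes vectors `√(Q̄² + Ū² + V̄²)` per
  incident polarization channel, averaged over the two channels. Low
  values mark depolarizing tissue such as pigmented skin.
* **OCTA decorrelation** — `1 − ρ` with the windowed complex correlation
  `ρ_ij = |Σ E_i E_j*| / √(Σ|E_i|² Σ|E_j|²)` over adjacent repeat pairs;
  flowing blood redraws the speckle between repeats and decorrelates.

Downstream of the contrasts it provides: rule-based segmentation of the
upper tail musculature on intensity B-scans; per-animal masked summary
statistics and the birefringence-abnormality fraction (percentage of
muscle voxels with `Δn < 0.0006`); exact/approximate Mann-Whitney rank
sum tests; Kaplan-Meier curves with the observed-over-expected hazard
ratio `HR = (O_C/E_C)/(O_T/E_T)` and log-rank test; and en-face vessel
metrics (vessel density in %, mean skeleton segment length in mm).

Because raw in-vivo volumes are rarely shareable, the package includes a
first-class phantom module: a zebrafish-tail tissue model (skin, dorsal
musculature, embedded tumor ellipsoid, vessels) propagated through a
per-voxel linear-retarder cascade, rendered with fully developed speckle,
repeat structure and shot noise — so every stage of the analysis is
testable against known ground truth, including a simulated 10-control /
13-tumor longitudinal cohort imaged at 7/11/15/19/21 days
post-injection.

## Worked example

```r
library(jmoct)

g <- AcquisitionGeometry(nDepth = 128, nFast = 96, nSlow = 12)
phantom <- buildPhantom(g, nz = 128, nx = 96, ny = 12, seed = 1)
jones <- renderMeasurement(cumulativeJones(phantom, seed = 2),
                           acqGeometry(phantom), snrDb = 25,
                           flowMask = truthMask(phantom, "vessel"),
                           seed = 3)
contrasts <- computeContrasts(jones)
contrasts
#> ContrastSet: 128 x 96 x 12 (z, x, y)
#>   intensity [-30.8, 6.8] dB, 73.6% valid
#>   birefringence [0, 0.0127], DOPU median 0.983
#>   OCTA decorrelation median 0.002

mask <- segmentUpperMuscle(contrasts)
segmentationAccuracy(mask, truthMask(phantom, "upper_muscle"))$dice
#> [1] 0.9652227

maskedMeans(contrasts, mask, bscanWindow = 12)
#>   mean_intensity_db mean_birefringence mean_dopu n_voxels
#> 1         -7.649678        0.001474488 0.9726653    54619

abnormalityFraction(contrasts, mask)
#> [1] 14.31278
```

The segmentation recovers the upper musculature with Dice 0.965 against
the phantom truth. The reliability-weighted mean birefringence over the
segmented muscle, 1.47 × 10⁻³, recovers the phantom's muscle value of
1.5 × 10⁻³ to within 2%; the abnormality fraction (14.3%) counts the
mask voxels pulled below the 6 × 10⁻⁴ threshold by the embedded
low-birefringence tumor plus speckle noise. `runPipeline()` chains the
same steps with the cohort simulation, group rank-sum comparisons,
survival analysis and vessel metrics into one deterministic, seeded run.

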