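---
title: "Models and methods behind jmoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jmoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jmoct)
```

This vignette explains the physical and statistical models the package
implements, the choices made where the design was genuinely open, and
what passing the test suite does — and does not — establish about real
measurements.

## The measurement model

A Jones-matrix OCT system records, per voxel, a complex 2 × 2 matrix
$J(z,x,y)$ describing how the sample transforms the two incident
polarization states, with $R$ repeated B-scans per slow-axis location
(default $R = 4$, inter-scan time 12.8 ms). The emulated acquisition
geometry (`AcquisitionGeometry()`) mirrors a 1.31 µm swept-source
prototype: 6 × 8 mm field of view, 512 × 128 lateral pixels, 7.24 µm
depth pitch, 14.0/18.1 µm axial/lateral resolution, 36 mm scan lens with
a 3.5 mm beam. All derived quantities (pixel pitches, effective OCTA
frame rate, numerical aperture, the retardation-to-birefringence scale)
are computed on demand and never stored, so they cannot drift out of
sync. Display rounding is half-up to the conventional number of
decimals; the numerical aperture is truncated rather than rounded
(0.04861 prints as 0.048, matching how such apertures are quoted).
Internally every value keeps full precision. The lateral resolution is a
stored instrument constant: it is not derivable from the quoted NA and
wavelength by a standard Gaussian-beam formula, so the package makes no
attempt to compute it.

Axes are fixed package-wide as `(repeat, depth z, fast x, slow y)` with
depth increasing away from the probe; one convention everywhere
prevents silent transposes.

## The phantom: what it emulates

`buildPhantom()` constructs a labelled voxel model of a sagittal block
of the zebrafish tail at the injection site: water background, a thin
pigmented skin layer on a gently undulating surface, the tail
musculature beneath it, an optional tumor ellipsoid that replaces muscle
voxels only (a graft grows inside the musculature), and a few straight
vessels along the fast axis in the upper musculature. Each tissue class
carries a linear backscatter coefficient, a birefringence $\Delta n$, an
optic-axis orientation, a depolarization strength and a flow flag
(`tissueCatalogue()`).

The default optical properties are invented but directionally
constrained by what is seen in vivo: muscle $\Delta n = 1.5\times
10^{-3}$ versus tumor $2\times 10^{-4}$ (ordered fibres versus
disorganized cell mass), tumor reflectivity twice muscle (densely packed
cells scatter more), skin depolarization strength 0.8 (pigment). They
are configurable; the defaults are the study conditions all tests run
under.

Light propagation (`cumulativeJones()`) treats every voxel as a linear
retarder $L_k = R(\theta_k)\,\mathrm{diag}(e^{+i\varphi_k/2},
e^{-i\varphi_k/2})\,R(-\theta_k)$ whose round-trip retardation per depth
pixel is $\varphi_k = 4\pi\,\Delta n_k\,\Delta z/\lambda_c$; the matrix
observed at depth $z$ is $\sqrt{\rho_z}\,L_z\cdots L_1$ with
backscatter $\rho_z$. Depolarization is modelled as sub-resolution
optic-axis scrambling — a zero-mean Gaussian perturbation of
$\theta_k$ with standard deviation `depolarization` · π/3 — which stays
entirely inside the Jones formalism while still driving DOPU down in
pigmented tissue. A Mueller-calculus depolarizer would be more general
but could not be propagated through the Jones pipeline being tested.

`renderMeasurement()` multiplies the noiseless matrices by a single
complex circular-Gaussian speckle field shared by all four entries
(static tissue keeps one realization across repeats; flow voxels redraw
it per repeat) and adds complex white noise with per-entry mean power
$\mathrm{floor} = \bar S\,10^{-\mathrm{SNR}/10}$, where $\bar S$ is the
mean tissue signal. The scalar speckle model is the simplest one that
leaves birefringence and DOPU recoverable (a common factor cancels in
eigenvalue phase splits and normalized Stokes vectors) while giving the
angiography a well-defined static/flow contrast, and it produces the
exponential intensity statistics of fully developed speckle, which the
test suite verifies.

What the phantom deliberately does **not** model: multiple scattering
(the reason the analysis restricts itself to the *upper* musculature in
the first place), motion artifacts, refraction at the skin, the source
spectrum, sensitivity roll-off, and vessel pulsatility. Tests passing on
phantoms therefore demonstrate the correctness and calibration of the
*analysis*, not the absence of these physical confounders in real data.

## Contrast computation

* **Intensity**: mean over repeats of
  $(|J_{11}|^2+|J_{12}|^2+|J_{21}|^2+|J_{22}|^2)/4$ in dB, clamped to a
  floor; a validity mask flags voxels above the floor plus a margin
  (default 6 dB).
* **Local birefringence**: repeats are averaged, then
  $J_{loc}(z) = J(z+\delta z)J(z)^{-1}$ over an axial separation of
  $\delta z = 1$ pixel. The retardation is the eigenvalue phase split
  wrapped to $[0, \pi]$; the wrap tie at $\pi$ resolves to $\pi$, the
  measurable ceiling $\lambda_c/(4\Delta z) = 0.0452$. Voxels with a
  singular local matrix (sub-floor intensity) get $\Delta n = 0$ with
  reliability 0 by convention, as do the last $\delta z$ depth planes.
  The estimator slot is pluggable: the default eigen-analysis can be
  replaced by, e.g., a maximum a posteriori estimator with the same
  signature, since phantom recovery — not a specific estimator — is the
  accepted surface. Reliability is the monotone SNR function
  $\max(0,\,1 - 1/\mathrm{SNR}_{rel})$, zero at or below the margin;
  downstream means are reliability-weighted.
* **DOPU**: computed per incident polarization channel from the
  repeat-averaged matrices (per-channel-then-average; whether real
  systems combine channels first is instrument-specific, so this is a
  configurable choice), with a default kernel of 5 (z) × 5 (x) × 1 (y)
  pixels — a common practice scale, not a measured constant.
  Zero-intensity voxels are excluded from the kernel; an all-excluded
  kernel returns 1 by convention and is flagged.
* **OCTA**: adjacent repeat pairs (they share the shortest inter-scan
  time) with a 5 × 5 window in the B-scan plane; the complex field is
  the coherent sum of the first Jones column. Taking the modulus of the
  windowed cross-term makes the measure exactly invariant to global
  phase drift between repeats. The decorrelation is masked by the
  intensity validity mask to separate tissue from background.

## Segmentation

The reference segmenter is deliberately rule-based and deterministic:
per B-scan, Otsu thresholding restricted to valid pixels, morphological
closing (disc of 5 px), largest connected component, then per A-line the
band from the detected tissue surface to the axial midline of the tissue
extent. "Upper half" is defined per A-line because the tail surface is
curved; the definition is configurable. A learned encoder-decoder
segmenter can implement the same B-scan-to-binary-mask contract (the
`MaskVolume` provenance field distinguishes `rule_based`, `learned`,
`truth`, `manual`), but no network is trained here: reference weights
and training data for the in-vivo task are not distributable, and the
phantom ground truth makes the downstream quantification testable either
way. Published in-vivo accuracies of learned segmenters are therefore
neither reproduced nor claimed.

## Quantification and statistics

Per-animal summaries are means over the masked voxels of the central 30
B-scans (the injection-site window; the centering rule is a convention
and configurable), with birefringence reliability-weighted. The
abnormality statistic is the percentage of masked voxels with $\Delta n$
below 0.0006 — counting only voxels with positive reliability, since
noise-dominated pixels would otherwise inflate the "abnormally low"
area.

The Mann-Whitney test uses midranks and switches between full
enumeration of all $\binom{n}{n_a}$ assignments (pooled $n \le 12$,
exact even under ties) and the normal approximation with tie and
continuity correction. Box-whisker summaries use type-7 (linear
interpolation) quantiles and Tukey 1.5 · IQR whiskers by default, with a
min-max option. No multiple-testing correction is applied across
imaging days by default, matching per-timepoint reporting practice; a
`pAdjustMethod` flag adds one.

Survival uses the product-limit estimator with right censoring at study
end (day 21 — animals alive at termination are censored, not events)
and the standard log-rank table with aggregated tie handling. The hazard
ratio is the observed-over-expected *event* ratio
$(O_C/E_C)/(O_T/E_T)$ — the only reading under which HR ≈ 1 means "no
survival difference" — with the usual $\sqrt{1/E_C + 1/E_T}$ log-scale
interval. A group with zero events yields a degenerate ratio with an
infinite confidence bound and a warning rather than an error, because a
small cohort can legitimately end with no deaths in one arm.

## Cohort simulation

`cohortSpec()` encodes the study design: 10 control and 13 tumor
animals, imaging at 7/11/15/19/21 days post-injection. Death times are
exponential with per-group hazards calibrated so that about 20% of
control and 39% of tumor animals survive to day 21 (hazards
$\ln 5/21$ and $\ln(1/0.39)/21$ per day). An exponential process cannot
simultaneously reproduce a high early survival plateau and a late
collapse; the calibration targets the day-21 endpoints that drive the
survival analysis, so simulated mid-study group sizes run smaller than a
plateau-shaped process would give. Group effect sizes (tumor minus
control) are configurable defaults — no quantitative group means are
published for this design, box plots only — chosen once to rise as the
graft establishes and fade as both groups deteriorate: intensity
+0.8…+2.6 dB peaking mid-study, birefringence −1×10⁻⁴…−4×10⁻⁴, DOPU
first lower then higher, abnormality +3…+12 percentage points, vessel
metrics slightly and non-significantly reduced. Animal-to-animal
variation is folded into a single within-group standard deviation per
quantity; no per-animal random slopes or baseline drift of the control
group over time are modelled.

## Numerical choices and degenerate inputs

* Box sums and Gaussian kernels truncate at the array boundary and
  renormalize, so constant fields are preserved exactly and no padding
  values are invented; Gaussian kernels truncate at 3σ.
* 2 × 2 eigenvalues use the closed form
  $(\mathrm{tr} \pm \sqrt{\mathrm{tr}^2 - 4\det})/2$; phase differences
  are wrapped via $|\arg(\lambda_1/\lambda_2)|$, which is exact across
  the ±π branch cut.
* OCTA power sums reuse the same complex products as the cross-term so
  that identical repeats give zero decorrelation at machine precision.
* Skeletons come from Zhang-Suen thinning; because thinning erodes
  segment ends by roughly the vessel half-width, endpoints are extended
  along their local direction to the mask boundary before lengths are
  measured. Path length sums 8-connected steps with anisotropic pixel
  pitches (11.72 µm fast × 15.63 µm slow at the default geometry);
  segment counts split the skeleton at pixels with ≥ 3 skeleton
  neighbors.
* Containers are single versioned RDS files with a schema tag; reads
  verify the tag and fail loudly on truncation. Complex volumes
  round-trip losslessly.

## Problem sizes

The generator's default grid is 256 (z) × 256 (x) × 32 (y). The test
suite and the acceptance script run on reduced grids — typically
128–160 (z) × 64–128 (x) × 8–16 (y) with 4 repeats, and 400–10⁴
replicates for Monte-Carlo calibration — sizes chosen so a full run
completes on a single desktop CPU in a few minutes while keeping ≥ 10⁴
voxels per tissue class for the distributional checks. All sizes are
explicit function arguments.

## Known limitations

* The birefringence estimator is eigen-analysis with SNR gating, not a
  full maximum a posteriori estimator; at 25 dB SNR its
  reliability-weighted muscle-mean bias on phantoms is several percent
  (upward, from noise-induced retardation), which the 10% recovery
  criterion absorbs but a MAP estimator would reduce.
* The rule-based segmenter assumes a single dominant tissue component
  per B-scan and a roughly horizontal surface; it is a reference
  implementation for phantoms, not a replacement for a trained model on
  real anatomy.
* Vessel metrics quantify a binary en-face mask; with an inter-scan
  time of 12.8 ms the underlying decorrelation under-samples slow flow,
  so absolute densities on real data depend on acquisition timing in
  ways the phantom does not capture.
* The cohort simulator draws group-level summaries directly; it does
  not render one image volume per animal and timepoint, so
  image-to-summary error propagation is exercised only through the
  single phantom analyzed alongside the cohort.
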