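---
title: "Methods: DSC perfusion nCBV measurement and its reproducibility on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSC perfusion nCBV measurement and its reproducibility on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dscrepro` implements a complete dynamic-susceptibility-contrast (DSC)
perfusion-MRI analysis chain for brain-tumor blood-volume measurement —
concentration conversion, gamma-variate first-pass fitting, contrast-leakage
correction, relative and normalized cerebral blood volume (rCBV/nCBV)
mapping, rigid mutual-information coregistration, manual and semiautomatic
(EM Gaussian-mixture) tumor segmentation — together with a seeded digital
phantom and observer simulator, so that the intra-/interobserver
reproducibility of the two segmentation workflows can be studied end-to-end
without clinical data. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and the places where
the design was genuinely open.

## 1. Signal model and perfusion quantification

**Concentration.** During bolus passage the gradient-echo signal obeys
$S(t) = S_0\,e^{-TE\,\Delta R_2^*(t)}$, so the package converts each voxel
with $\Delta R_2^*(t) = -\ln\!\big(S(t)/S_0\big)/TE$. $S_0$ is the mean of
the baseline window: frames 2..`baseline_points` (default 8). Frame 1 is
always excluded because the first excitation is not at steady state; the
protocol literature is silent on the exact window, so this is a package
convention. Voxels with a nonpositive baseline or any nonpositive sample
are flagged invalid and carried as `NA` — never an exception, since air
voxels are expected to fail.

**Gamma-variate first pass.** The first pass is modeled as
$C(t) = k\,(t-t_0)^{\alpha} e^{-(t-t_0)/\beta}$ for $t > t_0$ (zero
before), the canonical bolus shape whose integral
$k\,\beta^{\alpha+1}\Gamma(\alpha+1)$ is available in closed form and whose
peak sits at $t_0 + \alpha\beta$. Fitting suppresses recirculation and
late leakage because only the first pass is fitted: bolus arrival is
detected as the first frame exceeding baseline mean + 3 SD, and the fit
window ends at the first post-peak frame below 20% of the peak. The
single-curve fitter runs a log-spaced grid over $(t_0, \alpha, \beta)$
(the amplitude is solved linearly for each shape) followed by a
Nelder-Mead polish; flat or negative curves return a non-converged result
with `k_amp = 0`. The map-level fitter exploits that all voxels of one
acquisition share bolus timing: each candidate shape admits a linear
amplitude solve for every voxel at once, and each voxel keeps its
best-scoring shape. Because the amplitude is exact given the shape,
between-tissue CBV *ratios* are insensitive to modest shape-grid
discretization.

**Leakage correction.** In leaky tumor voxels extravasation biases the
integral. The package uses the standard two-parameter linear correction
against a non-enhancing reference curve $\bar C(t)$ (the mean over
white-/gray-matter voxels, at least 100 required):
$$C_v(t) \approx k_1 \bar C(t) - k_2 \int_0^t \bar C(\tau)\,d\tau,$$
fitted by least squares (one shared 2×2 normal-equation solve serves the
whole map), and the corrected curve adds the estimated leakage term back.
$k_2 = 0$ reproduces the input up to the scale $k_1$.

**CBV maps.** `compute_cbv_map()` integrates, per voxel, either the raw
curve (`raw`), the fitted gamma-variate in closed form (`gamma_fit`), or
the leakage-corrected curve (`leakage_corrected`). All time integrals are
trapezoidal on the time vector (nonuniform-capable), so results are
bit-reproducible. Negative integrals — possible under noise — are clipped
to zero and counted in a QC field. The study runner defaults to
`leakage_corrected`: the commercial tools this emulates do not document
whether they integrate the fitted curve or the corrected raw curve, so
both orders are offered through `mode` and the corrected-raw route is the
packaged default (it is vectorizable and unbiased for the phantom's
recirculation model, which scales with the first pass).

**Normalization.** Two schemes, mirroring the two workflows. *Manual*:
division by the mean rCBV of a reader-placed contralateral
normal-appearing-white-matter (NAWM) ROI, with the protocol constraints
enforced as validation errors — at least 40 mm² per slice, no gray-matter
voxels inside. *Automatic*: division by the mean rCBV of brain voxels
outside the tumor VOI, the observer-independent scheme of the
semiautomatic workflow. Both are invariant under global rescaling of the
map.

## 2. Segmentation workflows

**Manual.** The mass margin is outlined on each axial plane; voxels whose
centers fall inside the polygon (even-odd rule) form the slice ROI. The
mass mean nCBV is the *unweighted average of per-slice means* — the
protocol averages "values from every plane", not voxels. The mass SD is
correspondingly the plane average of per-slice SDs by default; a
voxel-pooled SD is available via `sd_rule = "pooled"` since the original
pooling rule is not documented. Slices with fewer than two voxels
contribute SD 0 and a QC count. Manual tumor volume uses the ellipsoid
approximation $V = 0.5 \cdot AP \cdot SI \cdot TR$ (ml for cm inputs).

**Semiautomatic.** An ellipsoidal VOI is adjusted around the mass; within
it, per-voxel feature vectors — (structural intensity, nCBV), each
z-scored inside the VOI — are clustered by a full-covariance Gaussian
mixture fitted with EM (`k` = 3..7, default 7, matching the segmentation
tool this emulates). Initialization is seeded farthest-point center
picking; covariances carry an $\varepsilon I$ ridge so constant features
cannot abort a fit; the log-likelihood trace is recorded and
non-decreasing; voxels take hard maximum-posterior labels, so clusters
partition the VOI. The feature pair is the minimal choice that lets
clusters separate necrosis (structural axis) from vessels (perfusion
axis); the channels are configurable because the commercial tool's exact
feature set is unpublished.

**Cluster selection.** The readers' visual selection of "clusters
reflecting true tumor tissue" is replaced by a deterministic surrogate so
the experiment is mechanizable: (i) the cluster that is jointly lowest in
mean structural intensity *and* mean nCBV is excluded (necrosis/cyst
surrogate); (ii) clusters whose mean nCBV exceeds `vessel_factor` (2)
times the next-highest cluster mean are excluded (macrovessel surrogate);
(iii) of the remainder, clusters below `retain_frac` (0.5) of the highest
remaining mean are dropped (perfused-core surrogate — normal parenchyma
and edema swept into the VOI are recognizable as non-tumor and would not
be selected by a reader). Rule (iii) was added after the two exclusion
rules alone proved insufficient: without it the semiautomatic mean is
dominated by how much normal brain the VOI happens to enclose, i.e. by
VOI size rather than tumor tissue, which contradicts the workflow being
modeled. The retention reference considers only clusters holding at least
`min_frac` (5%) of the VOI: a tiny cluster is a focal structure (a
vessel), not a tissue class, and must not define the tumor level. If the
rules would exclude everything (e.g. indistinguishable clusters), the
median-mean cluster is kept with a QC flag. Semiautomatic mass statistics
pool all voxels of the selected clusters, and the cluster volume is the
selected voxel count times the voxel volume.

## 3. Registration

Perfusion maps and structural images are aligned by rigid
mutual-information maximization: MI in bits from a 32-bin equal-width
joint histogram, a translation grid (±5 voxels), cyclic per-parameter
grid descent over rotations (±10°, 2° then 0.5° steps) and sub-voxel
translations (0.25 voxel), then a Nelder-Mead polish — all deterministic.
Bins and optimizer are package choices; the emulated software does not
publish its own. Masks are resampled with nearest-neighbor, intensity
maps trilinearly; out-of-field voxels become `NA`. Phantom studies are
generated aligned, so the study runner treats registration as an
identity-check stage; the module exists to honor the full pipeline and is
exercised by its own recovery tests.

## 4. The digital phantom

The phantom emulates the acquisition this pipeline targets: TR 1.5 s, TE
30 ms, 60 dynamic frames, voxel 1.875 × 1.875 × 5 mm³, on a 48 × 48 × 12
grid (a desk-scale field of view holding one hemisphere-lateralized mass).
Labeled compartments: NAWM, gray-matter shell, solid tumor sphere,
necrotic core, perilesional edema shell, intralesional macrovessel,
background. Default blood-volume ratios (NAWM = 1): gray matter 2.0,
solid tumor 4.5, necrosis 0.3, edema 0.8, macrovessel 12 — ordinary
values for high-grade glioma imaging, with the tumor value drawn
log-normally (median 4.5, log-SD 0.5, clamped to [1.5, 15]) across cohort
masses so that between-mass variance resembles a glioblastoma cohort's.

All tissues share the bolus shape ($t_0$ 15 s, $\alpha$ 3, $\beta$ 1.5 s)
with amplitude proportional to true CBV; a recirculation bolus carrying
25% of the first-pass area follows 8 s later with doubled $\beta$. Because
recirculation scales with the first pass, raw integrals preserve
between-tissue ratios — a deliberate simplification that makes the
forward model analytically invertible. Only solid tumor leaks
($k_2$ = 0.01 s⁻¹), with T1-dominant sign by default (apparent
concentration decreases; a flag generates the T2*-dominant case). Noise
is additive Gaussian on signal magnitude at baseline SNR 50 (Rician
optional; at SNR ≫ 1 the Gaussian approximation is adequate). Brain CBV
is modulated by a smooth random field (SD 12%) so that reference-ROI
placement genuinely matters. Structural images render each tissue at a
fixed intensity plus noise: CE-T1WI separates compartments (enhancing
tumor 220, necrosis 60, edema 90), while the T2WI contrasts overlap
(tumor 170, edema 185, necrosis 195) — the overlapping-T2-contrast
situation that makes T2-guided cluster selection harder, encoded as a
property of the modality rather than tuned per experiment.

**What the phantom does not model:** k-space/pulse-sequence effects,
motion, field inhomogeneity, partial-volume mixing at tissue borders,
infiltrative (non-spherical) tumor margins, arterial input function
variability. Passing tests therefore demonstrate internal consistency of
the estimators and the *mechanisms* of observer variability, not clinical
performance on real tumors.

## 5. The observer simulator and the study design

Each simulated reader outlines the mass on every slice: the true boundary
polygon (traced along voxel edges, so zero perturbation reproduces the
true mask exactly) is displaced radially by a smooth angular field —
a constant plus three Fourier harmonics with pointwise SD
`boundary_jitter_mm` (default 1 mm; a placeholder magnitude, exposed in
config, since no quantitative observer-variability measurements exist for
this protocol) — plus a systematic per-reader bias (±0.75 mm in the
packaged study: one reader outlines generously, the other tightly). On
T2WI the jitter is inflated by 1.5, reflecting the blurrier mass margin.
Excluded tissue (necrosis, vessels, edema) inside the outline is removed,
each voxel wrongly retained with `inclusion_error_rate` (default 0.05).
The NAWM reference ROI is a 4 × 4-voxel square (56 mm² > 40 mm²) placed at
the mirrored tumor position with 4 mm Gaussian placement jitter and
snapped to the nearest all-NAWM position — by construction it satisfies
the protocol constraints. The VOI is the smallest axis-aligned ellipsoid
covering the jittered mass.

The study runner executes the full design — 2 observers × 2 sessions ×
{manual, semiautomatic} × {CE-T1WI, T2WI} — yielding 16 records per mass
(8 measurement occasions per reader; intra- and interobserver tables both
need all 16 cells). Sessions differ only by the observer's random seed,
the simplest model of re-measurement after a washout interval. Every seed
derives deterministically from one master seed, so the whole experiment
is bit-reproducible.

The mechanisms that differentiate the workflows are explicit: manual
measurements inherit variance from reference-ROI placement (heterogeneity
field + noise on a 16-voxel mean), while the semiautomatic workflow
normalizes over the whole brain and selects clusters that are stable
against VOI perturbation on CE-T1WI; on T2WI the overlapping contrasts
and inflated margin uncertainty degrade it. The packaged 20-mass default
study reproduces the expected qualitative ordering — semiautomatic
CE-T1WI best interobserver cell, semiautomatic intraobserver above manual
on both structural images — and the acceptance script recomputes exactly
these quantities.

## 6. Statistics

Agreement between paired measurements uses the two-way random-effects,
absolute-agreement, single-measure ICC (the standard test-retest form;
the original analysis software's variant is not documented, so the
variant is stated in output metadata and a consistency ICC is available
by flag), with the F-distribution 95% CI and the published categories
(< 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, > 0.74 excellent).
CV is 100 × SD/mean per pair (sample SD), aggregated across masses by
root-mean-square — the squared-CV average matching the variance scale;
plain-mean aggregation is a flag, since the source formula is ambiguous
at cohort level. Bland-Altman limits of agreement use the conventional
1.96 multiplier. Paired t-tests are two-tailed at α = 0.05;
Kolmogorov-Smirnov normality uses the sample mean/SD. Degenerate inputs
(zero variance, nonpositive pair means) are flagged, not silently
dropped.

## 7. Numerical conventions and problem sizes

Voxel coordinates are voxel-index space with axial slices along the third
axis; voxel centers sit at (i − ½)·voxel size; masks are voxel sets;
serialized ROIs are 0-based, polygons in mm. Time integrals are
trapezoidal; EM convergence is relative log-likelihood change < 1e-6 with
a 200-iteration cap; covariance ridge 1e-6 of the mean feature variance;
EM ties in hard assignment break to the lowest cluster index. Tests run
on reduced instances (36 × 36 × 8 × 40 phantoms, 3–4-mass cohorts) chosen
so the full suite exercises every code path at interactive speed; the
packaged study default is 20 masses at the full 48 × 48 × 12 × 60
geometry, the size whose results the acceptance script reports.

## 8. Known limitations

The observer model is radial and smooth — it cannot produce topology
errors (split/merged regions) real readers occasionally make. The
selection surrogate is deterministic; reader idiosyncrasy enters only
through geometry seeds and the systematic bias term. Absolute nCBV levels
differ between the two workflows by construction (different
normalization references), so only agreement statistics — not method
means — should be compared across methods. The ICC CI formula assumes
balanced complete pairs. No arterial-input-function deconvolution is
provided (CBF/MTT are out of scope); the pipeline quantifies integral
rCBV only.
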