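# dscrepro

Reproducibility analysis of cerebral blood-volume measurement from dynamic
susceptibility contrast (DSC) perfusion MRI in brain tumors.

## The problem

DSC perfusion MRI tracks the signal drop during a gadolinium bolus with
fast T2\*-weighted imaging; the area under the concentration curve
ΔR2\*(t) = −ln(S(t)/S₀)/TE gives relative cerebral blood volume (rCBV),
and normalizing by a reference tissue gives nCBV, a standard marker of
glioma neovascularity. The measured value, however, depends on *who*
segments the tumor and *how*: a reader can outline the mass slice-by-slice
on a structural image (manual workflow, normalized by a contralateral
normal-appearing-white-matter ROI), or adjust an ellipsoidal VOI and let an
EM Gaussian-mixture clustering partition it into 3–7 tissue clusters from
which tumor clusters are selected (semiautomatic workflow, normalized
automatically by the mean rCBV outside the tumor). Which workflow, paired
with which structural image (contrast-enhanced T1 or T2), yields the most
reproducible nCBV is an experimental question — and answering it requires
repeated measurements by multiple observers.

`dscrepro` implements the full measurement chain in R and, because no
clinical cohort is shipped with it, a seeded digital phantom plus observer
simulator so the whole 2 observers × 2 sessions × 2 methods × 2
structural-images experiment runs end-to-end on synthetic glioblastoma-like
masses with known ground truth:

- **phantom** — 4D DSC studies (TR 1.5 s, TE 30 ms, 60 frames, voxel
  1.875×1.875×5 mm³) with labeled compartments (NAWM, gray matter, solid
  tumor, necrosis, edema, macrovessel), gamma-variate bolus + recirculation
  + tumor contrast leakage, and simulated reader delineations;
- **perfusion** — concentration conversion, gamma-variate first-pass
  fitting C(t) = k(t−t₀)^α e^{−(t−t₀)/β}, two-parameter Boxerman-type
  leakage correction trace ≈ k₁·ref − k₂·∫ref, rCBV/nCBV maps under both
  normalization schemes;
- **registration** — rigid coregistration by mutual-information
  maximization;
- **segmentation** — per-slice polygon ROIs with plane-averaged statistics,
  and VOI + EM full-covariance Gaussian mixture (k = 3..7, default 7) with
  a deterministic cluster-selection surrogate;
- **reproducibility** — ICC (two-way random, absolute agreement, single
  measures; 95% CI; published categories), coefficient of variation
  (100×SD/mean), Bland-Altman limits of agreement, paired t-test,
  Kolmogorov–Smirnov normality, and the study runner producing the
  intra-/interobserver agreement tables.

See `vignettes/dsc-reproducibility-methods.Rmd` for the models, defaults
and design decisions.

## Worked example

One phantom mass, manual workflow:

```r
library(dscrepro)

spec  <- phantom_spec(rng_seed = 42L)                # defaults: SNR 50, leaky tumor
study <- generate_phantom(spec)
conc  <- signal_to_concentration(study$dynamic)
cbv   <- compute_cbv_map(conc, mode = "leakage_corrected",
                         labels = study$truth_labels)
del   <- simulate_observer_rois(study, observer_spec(rng_seed = 1L), "ce_t1wi")
ncbv  <- normalize_manual(cbv, del$nawm_roi, study$truth_labels)
stats <- manual_mass_statistics(ncbv, del$manual_mask)
sprintf("manual mass nCBV: %.2f +/- %.2f over %d voxels",
        stats$mean_ncbv, stats$sd_ncbv, stats$n_voxels)
#> "manual mass nCBV: 5.29 +/- 0.67 over 577 voxels"
```

The mass mean nCBV of 5.29 says the delineated tumor has ~5.3× the blood
volume of the reader's white-matter reference ROI (this phantom's true
tumor/NAWM ratio is 4.5; the excess reflects reference-ROI placement on the
heterogeneity field, outline jitter, and noise — exactly the error sources
the reproducibility experiment quantifies).

A small reproducibility study (6 masses; the packaged default is 20):

```r
cfg <- default_study_config(n_masses = 6)
res <- run_reproducibility_study(cfg)
res$interobserver[res$interobserver$session == 1,
  c("method", "structural", "icc", "icc_lo", "icc_hi", "icc_category",
    "cv_percent")]
#>    method structural   icc icc_lo icc_hi icc_category cv_percent
#>    manual    CE_T1WI 0.922  0.532  0.989    excellent      10.36
#>    manual       T2WI 0.971  0.837  0.996    excellent       7.49
#>  semiauto    CE_T1WI 0.999  0.919  1.000    excellent       1.01
#>  semiauto       T2WI 0.998  0.986  1.000    excellent       1.92
```

Each row is one interobserver comparison cell (observer 1 vs observer 2,
first session) over the cohort: the semiautomatic workflow on CE-T1WI is
the most reproducible cell (highest ICC, lowest CV), and manual cells carry
roughly an order of magnitude more between-reader variation — driven in the
simulation by reference-ROI placement, as in practice. `res$intraobserver`,
`res$volume_interobserver` and `res$ncbv_summary` hold the corresponding
session-repeat, volume-agreement and cohort-summary tables, and
`res$measurements` the underlying 16-records-per-mass table.

A thin command-line wrapper over the same functions is installed at
`inst/cli/dscrepro.R` (`simulate` / `analyze` / `report` subcommands, YAML
config, NIfTI + JSON + CSV interchange).

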