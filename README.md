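# znppfluor

Non-invasive quantitation of erythrocyte zinc protoporphyrin (ZnPP) by
dual-wavelength fluorescence spectroscopy, for researchers in biomedical
optics and point-of-care diagnostics.

When iron is unavailable during haem synthesis, zinc is incorporated
into protoporphyrin IX instead, so the red-cell ZnPP/haem ratio (µmol
ZnPP per mol haem) is an established indicator of functional iron
deficiency. ZnPP fluoresces under blue excitation, and the blood-filled
capillaries under the thin epithelium of the lower lip can be probed
with an optical fibre — but the mucosal autofluorescence background is
roughly a hundredfold stronger than the ZnPP band. This package
implements the full computational chain that makes the measurement
quantitative, exercised entirely on synthetic and published data:

- **Difference spectroscopy.** Emission spectra are acquired at 425 nm
  (the ZnPP excitation maximum) and 407 nm (chosen for equal blood
  absorption). After normalising F₄₀₇ to F₄₂₅ over 520–525 nm and
  subtracting, the tissue background largely cancels while ~78% of the
  ZnPP signal survives (ZnPP is excited ~78% less efficiently at
  407 nm); protoporphyrin IX (PPIX) enters negatively.
- **Second-derivative spectral fitting.** Amplitudes (a, z, p) of the
  blood absorption imprint, the ZnPP template and the PPIX template are
  chosen so that the remaining background
  B(λ) = (D(λ) − z F_ZnPP − p F_PPIX) / exp(−a μ_a(λ))
  is maximally smooth over 560–750 nm, i.e. minimises Σ B″(λ)². The
  subject-specific background shape is never modelled — only its lack
  of sharp curvature is used.
- **Blood absorption index.** The haemoglobin dip imprinted on the
  407-nm autofluorescence around 576 nm, measured from bands at
  562/576/593 nm, qualifies tissue sites in real time (green zone at
  ≥ 0.70 × 10⁻²); only qualified sites preserve the proportionality
  between detected fluorescence and the ZnPP/haem ratio.
- **Vessel-packaging correction.** Blood confined in vessels of
  diameter d absorbs less than evenly distributed haemoglobin:
  C = (1 − e^(−μd))/(μd), with forward and numerically inverted forms.
- **Layered Monte Carlo.** An MCML-style photon transport code (Rcpp)
  with fibre source/detector, NA-limited launch and detection,
  reflecting ferrule, Henyey–Greenstein scattering, survival roulette
  with an exact energy ledger, and weighted direct fluorescence
  emission per tissue layer and fluorophore class.
- **Method-comparison statistics.** Robust zero-offset scaling to
  reference units, Bland–Altman limits of agreement from the robust
  τ-scale (×1.96) with percentile-bootstrap CIs, ROC-optimal (Youden)
  cutpoints, and diagnostic test metrics.
- **Synthetic data generator.** Seeded spectra, sessions and cohorts
  with the statistical structure the algorithm assumes, so every module
  is testable without any instrument data.

## Worked example

```r
library(znppfluor)
refs <- load_reference_library()

# one synthetic subject: 3 sites x 3 cycles, true amplitude 50
gs  <- spectrum_gen_spec(znpp_amplitude = 50, seed = 42)
ses <- generate_session(gs, refs, n_sites = 3, cycles_per_site = 3)
quantify_subject(ses, refs)
#> <znpp_subject_result> subject synthetic: mean z = 39.385 +/- 0.417 (s.e.m., n = 9)

f407 <- resample_spectrum(calibrate_cycle(ses$sites[[1]]$cycles[[1]])$f407,
                          refs$grid)
blood_absorption_index(f407, refs)[c("index", "zone")]
#> index 0.0119, zone green
```

The fitted mean of 39.4 is the ZnPP amplitude *in the difference
spectrum*: with the 0.22 excitation ratio of ZnPP at 407 nm the
difference retains 1 − k·0.22 ≈ 78% of the generated amplitude 50. The
site's blood absorption index (0.0119) is above the green threshold
(0.0070), so the site qualifies for quantitation. The conversion to
µmol/mol haem is estimated blindly from a paired cohort:

```r
co <- generate_cohort(cohort_gen_spec(seed = 7))      # 56 subjects
k  <- robust_proportional_slope(co$device_value, co$hplc_mean)
robust_bland_altman(co$device_value / k, co$hplc_mean,
                    n_boot = 2000, seed = 8)
#> <znpp_agreement> n = 56: bias 0.98, limits of agreement 16.30 (95% CI 10.60-20.64)

roc_optimal_cutpoint(co$device_value / k, co$hplc_mean > 50)
#> <znpp_diagnostic> sens 85.0%, spec 100.0%, PPV 100.0%, NPV 72.7% at threshold 63.4698
```

Limits of agreement of ~16 µmol/mol at device noise s.d. 19/1.96 are in
the expected range for n = 56 (the estimator's sampling spread at this
size is roughly ±15%).

A thin command-line wrapper ships in `inst/cli/znpp`
(`simulate | quantify | blood-index | mc | stats | end-to-end`); run it
as `Rscript inst/cli/znpp <command> ...` or see `?znpp_main`.

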