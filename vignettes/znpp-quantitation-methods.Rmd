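---
title: "Methods: dual-wavelength ZnPP quantitation, site qualification, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-wavelength ZnPP quantitation, site qualification, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znppfluor)
```

This vignette is the package's own account of the science it
implements: the measurement model, the fitting and site-qualification
procedures, the simulation machinery, the choices made where the design
was genuinely open, and what the synthetic tests do and do not
establish about real tissue data.

## The measurement model

Erythrocyte zinc protoporphyrin (ZnPP) accumulates when iron is
unavailable for haem synthesis; the ZnPP/haem molar ratio (µmol per
mol) is the reporting unit because the fluorescence detected from
blood — in a cuvette or in capillaries — is proportional to that ratio
rather than to the ZnPP concentration alone. The package's
`whole_blood_fluorescence_signal()` states this analytically for a
non-scattering absorbing half-space: detected fluorescence is
c/(µ_exc + µ_em), invariant under joint dilution of fluorophore and
haemoglobin because both absorption coefficients are haemoglobin-
dominated.

In tissue, spectra are acquired through a single fibre at two
excitation wavelengths with a dark spectrum per cycle. Calibration is
dark subtraction followed by normalisation to 1 ms
(counts → counts/ms). All cycle spectra are interpolated onto a common
1-nm grid spanning 500–750 nm. The grid is an assumption (the
instrument's native grid is not fixed by the method): 1 nm preserves
the narrowest features handled anywhere in the pipeline (haemoglobin
dips ~10 nm wide), and the band arithmetic — normalisation over
520–525 nm, fitting over 560–750 nm, index bands at 562/576/593 nm —
presumes a shared grid. Both limits and spacing are configurable
(`common_grid()`).

The difference spectrum is D = F₄₂₅ − k·F₄₀₇ with
k = mean(F₄₂₅; 520–525 nm)/mean(F₄₀₇; 520–525 nm). At these two
excitations capillary blood absorbs nearly identically and the tissue
volumes probed coincide, so the backgrounds are similar in shape and
the subtraction cancels most of the background while retaining
1 − 0.22k ≈ 78% of the ZnPP amplitude (ZnPP is excited ~78% less
efficiently at 407 nm). PPIX, excited more strongly at 407 nm, enters
with negative sign. Calibrated intensities may legitimately be
negative near the PPIX bands, so nothing is clipped anywhere.

## Second-derivative fitting

The fit removes three structured features from D — the ZnPP template,
the PPIX template, and the haemoglobin absorption imprint — by making
the remaining background

B(λ) = (D(λ) − z·F_ZnPP(λ) − p·F_PPIX(λ)) / exp(−a·µ_a(λ))

as smooth as possible over 560–750 nm, minimising the sum of squared
second derivatives of B. The background itself is deliberately not
modelled; tissue autofluorescence varies between subjects and sites
but lacks sharp curvature, whereas the porphyrin bands (25–40 nm) and
the haemoglobin dips are curvature-rich.

Numerical choices:

- **Savitzky–Golay pre-smoothing** (window 9, order 3, on by default)
  precedes the central second differences, because second differences
  amplify shot noise as h⁻². The window is small against the porphyrin
  bands; half a window is trimmed at each end of the fit window where
  the SG endpoint fits are transient.
- **Optimisation.** For fixed a the problem is exactly linear in
  (z, p), so the implementation profiles them out by least squares on
  the curvature images of the basis spectra, and searches a on
  [0, 0.05] mm with a 51-point deterministic grid followed by
  golden-section refinement (tolerance 1e-9). This replaces a generic
  simplex search: it is fully deterministic, cannot converge to a
  (z, p) side-minimum, and exploits the structure of the model. The
  reported objective is the profiled minimum; `converged` is always
  defensible because the scan is global over the bounded a-range.
- **Ordering.** Emission templates are subtracted *before* the
  absorption division; equivalently, the porphyrin amplitudes are
  detector-level quantities while the background carries the explicit
  absorption imprint. The synthetic generator uses the same ordering
  (bands added after the background is imprinted), keeping the
  generated amplitude identical to the quantity the fit estimates.
  The alternative ordering (bands attenuated together with the
  background) differs only by a band-shape distortion of order
  a·µ_a(593) ≈ 5% and is not separately identifiable from tissue data.

On noiseless generator output the fit recovers z and p to ~0.1% and a
to ~3%; at the default shot-noise level the mean of 200 replicate
estimates stays within 2% of truth (both checked in the test suite).

## Blood absorption index and site qualification

Sites are qualified by the magnitude of the haemoglobin dip imprinted
on the 407-nm autofluorescence near the 576-nm oxyhaemoglobin peak.
Three bands (562, 576, 593 nm; half-width ±3 nm, centres fixed by the
method, half-width a package default) are used: the index a ≥ 0 is the
effective haemoglobin path such that after dividing the *spectrum* by
exp(−a·µ_a(λ)) the central band mean falls on the straight line
between the flanking band means. The correction is applied per
wavelength before band averaging — µ_a varies steeply across the
593-nm band, and correcting band means at their centres instead leaves
a several-percent bias in the recovered index. The root is bracketed
on [0, 0.05]; if no sign change exists the spectrum is flat (no dip)
and the index is reported as 0 with a flag.

Since a multiplies the whole-blood µ_a curve (mm⁻¹), the index is an
effective haemoglobin path length in mm: the green threshold
0.70 × 10⁻² corresponds to ~7 µm of whole blood, i.e. an ~18% dip at
576 nm. Zones follow the instrument's LED table with thresholds closed
on the left of each upper zone (exactly 0.70 × 10⁻² is green); the
qualification decision `accept_site()` is green-only. A two-band
closed-form variant, a = ln(G₅₇₆/G₅₆₁)/(µ₅₆₁ − µ₅₇₆), is selectable
(`index.mode = "two_band"`); it is exact when the underlying baseline
is equal at both bands (the simulation context) but confounds
background slope with absorption on tissue spectra, which is why the
three-band form is the default.

Residual index bias on curved backgrounds is dominated by the
background's own curvature across 562–593 nm (a three-point scheme
cannot separate background curvature from absorption); with the
generator's default background this is ≤5% over the index range
0.002–0.02 and smallest in the green zone.

## Reference curves

The bundled whole-blood absorption curve is a natural cubic spline in
log µ_a through control points shipped in `inst/extdata`. The control
points at 561, 576 and 593 nm are *anchors* obtained by numerically
inverting the packaged 1%-blood, 24-µm working coefficients (0.153,
0.206, 0.056 mm⁻¹) through the van Veen relation — giving 19.07,
28.42 and 6.01 mm⁻¹ — and the 425-nm anchor (197.2 mm⁻¹) is kept as a
scalar outside the emission grid; between anchors the shape follows a
standard oxyhaemoglobin whole-blood spectrum. An anchor self-check
runs on every load; user-supplied curves deviating >25% warn rather
than fail.

Two bases coexist deliberately: the packaged working points imply
whole-blood µ_a(593) ≈ 6.0 mm⁻¹, while the non-packaged whole-blood
sample model uses 188.49 mm⁻¹ (425 nm) and 4.79 mm⁻¹ (593 nm) on a
96%/4% oxy/deoxy basis. The two sets are not mutually consistent —
they evidently assume different oxygenation — so each is bundled and
pinned to its own context (tissue simulation vs whole-blood sample
model) rather than reconciled.

Emission templates are parametric: ZnPP one Gaussian band at 593 nm
(FWHM 25 nm); PPIX bands at 635 nm (unit) and 705 nm (0.3 relative;
FWHM 25/40 nm). Peak positions are fixed by the spectroscopy of the
porphyrins; the widths are free parameters, and the same templates are
used to generate and to fit, so tests probe the estimator rather than
template misspecification. The PPIX 407/425 excitation ratio is only
constrained to exceed 1 by the physics; 2.0 is the configurable
default.

## Monte Carlo transport

The simulator is an MCML-style layered code with fluorescence by
weighted direct emission, written in C++ for throughput:

- Launch: uniform over the fibre face; cosine-weighted direction
  within the NA cone (sin²θ uniform), with the acceptance angle
  refracted into tissue (sin θ ≤ NA/n_tissue) and the fibre face
  treated as index-matched to wet mucosa. The same NA rule governs
  detection. Photons exiting within the fibre face but outside the
  acceptance cone are counted as lost (absorbed by the fibre
  cladding); whether the original instrument applied Fresnel
  reflection at the fibre face is not determinable, and the
  index-matched contact assumption is the documented default.
- Transport: extinction-sampled steps with per-layer
  Henyey–Greenstein scattering; continuous absorption weighting;
  Fresnel reflection (with total internal reflection) at the free
  surface outside the 12-mm perfectly reflecting ferrule annulus;
  transmission through the 10-mm lower boundary.
- Roulette: threshold 1e-4, survival 0.1 (standard constants), with an
  explicit roulette balance in the ledger so that
  detected + absorbed + escaped + transmitted + roulette ≡ 1 *exactly*
  on every run, not just in expectation.
- Fluorescence: at each absorption event a photon of weight
  (deposited × quantum yield), thinned unbiasedly by a spawn
  probability, is emitted isotropically and transported at the
  emission-wavelength properties; detected weight is tallied per
  source layer and fluorophore class (autofluorescence everywhere,
  ZnPP only in blood-perfused stroma), normalised per injected
  excitation photon. Fixed emission wavelengths (561/576/593 nm) stand
  in for full emission spectra; spectrally resolved fluorescence is
  the quantitation module's domain.
- RNG: each photon owns a xoshiro256++ stream keyed by (seed, photon
  index) via splitmix64 — reproducible and independent of execution
  order.

The three-layer mucosa builder (`default_tissue_model()`) places a
ZnPP-free epithelium (50–400 µm) over a 200-µm superficial stroma and
a 10-mm lower stroma differing only in blood content; blood enters the
absorption coefficients through the vessel-packaging correction at
425 nm and at the emission wavelength. Baseline (bloodless) optical
properties default to mid-range oral mucosa values (µ_a 0.1/0.03 mm⁻¹
and µ_s 20/15 mm⁻¹ at excitation/emission, g = 0.9); the original
optical-property sweep tables are not available, so sweep grids are
user-specified (`mc_sweep()`).

Problem sizes are desk-scale by design: validation uses 10⁶ photons
for the non-scattering Beer–Lambert and detection-geometry oracles
(where each photon takes O(1) steps) and 2–5 × 10³ photons with spawn
thinning for scattering fluorescence checks, with Monte Carlo standard
errors quoted in the assertions. Trend-level agreement (fibre-diameter
monotonicity, blood-index monotonicity in blood fraction) is what the
reduced budgets establish; they do not reproduce high-precision
absolute detection fractions for strongly scattering stacks.

## Synthetic data

`generate_spectrum_pair()` draws a smooth positive background through
control points, imprints exp(−a·µ_a), adds detector-level porphyrin
bands with the excitation-efficiency ratios, and converts to raw
counts with a dark offset and Gaussian noise whose variance is
proportional to intensity (shot-noise surrogate; Poisson exactness is
irrelevant at ≫10 counts). The default noise scale, 0.7 counts/ms at
the mean background level, corresponds to the shot noise of a
~100 counts/ms background integrated for 200 ms. The 407/425
background shape ratio r(λ) = exp(ε·P(λ)) (P a random cubic of unit
maximum, ε = 0.05) models the slight excitation dependence of the
background shape: with r ≡ 1 difference-spectrum suppression is exact,
and at the default ε the suppression at 593 nm is high but not total —
the regime the instrument exhibits.

`generate_session()` adds site-level random effects (log-normal
background scaling, blood-path jitter clamped to the green zone, a 5%
multiplicative site efficiency on z standing in for residual site
dependence) and can append sub-threshold and examiner-rejected sites.
`generate_cohort()` draws true ZnPP/haem values log-normally with the
log-mean set so that the deficient fraction (>50 µmol/mol) is 35/56 in
expectation and σ_log = 0.6 (a clinically plausible spread reaching
from the replete range to ~200 µmol/mol); device error is Gaussian
with s.d. 19/1.96 so that robust limits of agreement land near 19
µmol/mol, and HPLC triplicates carry a 5% CV, consistent with the
scale of inter-assay agreement reported for the reference method. The
hidden device scale (default 1 instrument unit ≡ 1 µmol/mol) is
re-estimated blindly by the scaling step, so the unit conversion
pipeline is genuinely exercised.

What passing synthetic tests show: the estimators invert their own
generative assumptions accurately and robustly at realistic SNR. What
they cannot show: template misspecification on real porphyrin spectra,
melanin or bilirubin interference, pressure- or motion-induced
perfusion changes, or detector nonlinearity — none of which the
generator emulates.

## Statistics

- The device-to-reference conversion is a zero-offset robust slope
  (bisquare IRLS from the median ratio, c = 4.685, MAD residual
  scale): zero signal must mean zero ZnPP, and gross outliers must not
  leverage the scale. Scaling and evaluation on the same cohort
  replicate the study design; the circularity is acknowledged and
  preserved for fidelity.
- Agreement uses the Maronna–Zamar τ-estimate (c₁ = 4.5, c₂ = 3.0,
  normal-consistency constant E[min(Z², (c₂·q₀.₇₅)²)] ≈ 0.9247): bias
  is the τ-location (coherent with the robust scale; the choice of
  location estimator is otherwise open) and the limits of agreement
  are 1.96 × τ-scale, with percentile-bootstrap CIs (default 2000
  resamples, seed mandatory; the bootstrap variant and replicate count
  are package defaults). Under 10% gross contamination the τ-scale
  remains bounded (~1.2 for outliers at +50, since each capped point
  contributes ρ = c₂²) while the classical s.d. explodes; it is not
  bias-free at that contamination level, and the tests assert the
  bounded behaviour it actually has.
- `loa_ci_halfwidth_factor()` is the standard large-sample
  approximation 1.96·√(3/n) for the CI half-width of a limit of
  agreement, ≈0.45·s at n = 56.
- The ROC cutpoint maximises Youden's J over all midpoints between
  adjacent distinct scores, ties broken toward higher specificity; the
  optimality criterion is a package decision where the study names
  only its software. An exhaustive brute-force scan and an external
  ROC implementation serve as test oracles.
- Iron status is deficient strictly above 50 µmol/mol; 40–50 is
  annotated as an indeterminate zone where elevations may reflect
  inflammation rather than iron deficiency.

## Known limitations

- The fitted a is weakly identified when the difference-spectrum
  residual background is very small (nearly identical excitation
  backgrounds): the absorption imprint then has almost no carrier. The
  index-based site qualification, not the fitted a, is the intended
  measure of blood content.
- The bundled absorption curve is anchor-exact but interpolated
  between anchors; spectral regions far from 560–600 nm carry little
  information in any of the algorithms.
- The Monte Carlo detects through a single fibre and models fixed
  emission wavelengths; time resolution, polarisation and GPU-scale
  photon budgets are out of scope.
- Melanin and bilirubin interference are not modelled anywhere in the
  package.
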