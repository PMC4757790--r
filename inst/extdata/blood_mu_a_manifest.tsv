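wavelength_nm	value_mm-1	provenance
425	197.2085	anchor: inverted from packaged 1%-blood coefficient 0.413 mm^-1 at 24-um vessels (van Veen relation); held as scalar, outside emission grid
561	19.0667	anchor: inverted from packaged coefficient 0.153 mm^-1 at 24 um, 1% blood
576	28.41706	anchor: inverted from packaged coefficient 0.206 mm^-1 at 24 um, 1% blood
593	6.013849	anchor: inverted from packaged coefficient 0.056 mm^-1 at 24 um, 1% blood
other	-	shape points following a standard oxyhaemoglobin whole-blood spectrum (peaks near 542/577 nm, steep fall beyond 585 nm), scaled to join the anchors smoothly; interpolated by a natural cubic spline in log(mu_a)
425_wb	188.49	whole-blood sample basis (96% oxy / 4% deoxy): excitation coefficient used for the non-packaged whole-blood model
593_wb	4.79	whole-blood sample basis (96% oxy / 4% deoxy): emission coefficient used for the non-packaged whole-blood model
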