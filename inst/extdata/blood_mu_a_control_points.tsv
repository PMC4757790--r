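# excitation_nm=dark
# integration_time_ms=1
# calibrated=true
# rows=22
wavelength_nm	intensity
500	11.2
510	11.0
520	13.0
530	17.5
542	29.5
550	25.0
556	21.0
561	19.0667
566	20.5
571	24.5
576	28.41706
580	24.0
585	14.0
593	6.013849
600	1.6
610	0.75
625	0.55
650	0.35
675	0.28
700	0.22
725	0.18
750	0.16
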