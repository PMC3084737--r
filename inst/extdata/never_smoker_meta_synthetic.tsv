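label	ancestry	cases_risk	cases_nonrisk	controls_risk	controls_nonrisk
primary-never-smokers	European	169	309	412	694
synthetic-study-A	European	210	350	700	1240
synthetic-study-B	European	95	160	310	540
synthetic-study-C	East-Asian	18	1020	55	4020
synthetic-study-D	European	160	290	520	930
synthetic-study-E	mixed	120	220	410	760
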