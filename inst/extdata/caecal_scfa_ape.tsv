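compound	mouse	timepoint	ape
acetate	M4	2h	2.7
acetate	M5	2h	0.1
acetate	M6	2h	24.6
acetate	M7	4h	6.5
acetate	M8	4h	20.1
acetate	M9	4h	3.3
propionate	M4	2h	NA
propionate	M5	2h	NA
propionate	M6	2h	NA
propionate	M7	4h	NA
propionate	M8	4h	NA
propionate	M9	4h	NA
butyrate	M4	2h	6.4
butyrate	M5	2h	0.4
butyrate	M6	2h	39.7
butyrate	M7	4h	14.8
butyrate	M8	4h	38.3
butyrate	M9	4h	8.0
lactate	M4	2h	6.1
lactate	M5	2h	0.0
lactate	M6	2h	38.8
lactate	M7	4h	3.8
lactate	M8	4h	0.7
lactate	M9	4h	0.4
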