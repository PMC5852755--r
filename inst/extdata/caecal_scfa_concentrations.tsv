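organic_acid	mouse	timepoint	concentration	below_limit
formate	M1	0h	0.3	TRUE
formate	M2	0h	0.3	TRUE
formate	M3	0h	0.3	TRUE
formate	M4	2h	0.3	TRUE
formate	M5	2h	0.3	TRUE
formate	M6	2h	0.3	TRUE
formate	M7	4h	0.3	TRUE
formate	M8	4h	0.3	TRUE
formate	M9	4h	0.3	TRUE
acetate	M1	0h	17.77	FALSE
acetate	M2	0h	16.6	FALSE
acetate	M3	0h	18.7	FALSE
acetate	M4	2h	18.7	FALSE
acetate	M5	2h	13.39	FALSE
acetate	M6	2h	6.69	FALSE
acetate	M7	4h	10.82	FALSE
acetate	M8	4h	7.27	FALSE
acetate	M9	4h	14.22	FALSE
propionate	M1	0h	4.9	FALSE
propionate	M2	0h	2.58	FALSE
propionate	M3	0h	3.08	FALSE
propionate	M4	2h	2.69	FALSE
propionate	M5	2h	1.71	FALSE
propionate	M6	2h	1.35	FALSE
propionate	M7	4h	1.6	FALSE
propionate	M8	4h	1.33	FALSE
propionate	M9	4h	1.75	FALSE
butyrate	M1	0h	5.65	FALSE
butyrate	M2	0h	4.72	FALSE
butyrate	M3	0h	4.19	FALSE
butyrate	M4	2h	4.25	FALSE
butyrate	M5	2h	3.04	FALSE
butyrate	M6	2h	1.96	FALSE
butyrate	M7	4h	3.74	FALSE
butyrate	M8	4h	2.14	FALSE
butyrate	M9	4h	4.12	FALSE
valerate	M1	0h	0.23	FALSE
valerate	M2	0h	0.17	FALSE
valerate	M3	0h	0.17	FALSE
valerate	M4	2h	0.26	FALSE
valerate	M5	2h	0.22	FALSE
valerate	M6	2h	0.13	FALSE
valerate	M7	4h	0.16	FALSE
valerate	M8	4h	0.12	FALSE
valerate	M9	4h	0.18	FALSE
caproate	M1	0h	0.1	TRUE
caproate	M2	0h	0.1	TRUE
caproate	M3	0h	0.1	TRUE
caproate	M4	2h	0.1	TRUE
caproate	M5	2h	0.1	TRUE
caproate	M6	2h	0.1	TRUE
caproate	M7	4h	0.1	TRUE
caproate	M8	4h	0.1	TRUE
caproate	M9	4h	0.1	TRUE
enanthate	M1	0h	0.1	TRUE
enanthate	M2	0h	0.1	TRUE
enanthate	M3	0h	0.1	TRUE
enanthate	M4	2h	0.1	TRUE
enanthate	M5	2h	0.1	TRUE
enanthate	M6	2h	0.1	TRUE
enanthate	M7	4h	0.1	TRUE
enanthate	M8	4h	0.1	TRUE
enanthate	M9	4h	0.1	TRUE
lactate	M1	0h	0.59	FALSE
lactate	M2	0h	0.96	FALSE
lactate	M3	0h	3.66	FALSE
lactate	M4	2h	0.94	FALSE
lactate	M5	2h	0.38	FALSE
lactate	M6	2h	0.8	FALSE
lactate	M7	4h	0.67	FALSE
lactate	M8	4h	0.25	FALSE
lactate	M9	4h	0.48	FALSE
succinate	M1	0h	0.52	FALSE
succinate	M2	0h	0.45	FALSE
succinate	M3	0h	0.82	FALSE
succinate	M4	2h	0.47	FALSE
succinate	M5	2h	0.32	FALSE
succinate	M6	2h	0.31	FALSE
succinate	M7	4h	0.33	FALSE
succinate	M8	4h	0.3	TRUE
succinate	M9	4h	0.3	TRUE
isobutyrate	M1	0h	0.25	FALSE
isobutyrate	M2	0h	0.15	TRUE
isobutyrate	M3	0h	0.19	FALSE
isobutyrate	M4	2h	0.22	FALSE
isobutyrate	M5	2h	0.15	TRUE
isobutyrate	M6	2h	0.15	TRUE
isobutyrate	M7	4h	0.15	TRUE
isobutyrate	M8	4h	0.15	TRUE
isobutyrate	M9	4h	0.15	TRUE
isovalerate	M1	0h	0.13	FALSE
isovalerate	M2	0h	0.1	TRUE
isovalerate	M3	0h	0.14	FALSE
isovalerate	M4	2h	0.13	FALSE
isovalerate	M5	2h	0.1	TRUE
isovalerate	M6	2h	0.1	TRUE
isovalerate	M7	4h	0.1	TRUE
isovalerate	M8	4h	0.1	TRUE
isovalerate	M9	4h	0.1	TRUE
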