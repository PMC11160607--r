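set	horvath_pan_tissue	horvath_skin_blood	hannum	phenoage
age_increasing_pc1	0	6	1	1
age_increasing_pc5	0	4	3	0
age_decreasing_pc1	0	0	0	1
age_decreasing_pc5	0	5	0	2
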