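clock	horvath_pan_tissue	horvath_skin_blood	hannum	phenoage
horvath_pan_tissue	353	60	6	41
horvath_skin_blood	60	391	45	58
hannum	6	45	71	6
phenoage	41	58	6	513
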