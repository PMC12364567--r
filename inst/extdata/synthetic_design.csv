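"sample_id","phenotype","compartment"
"F_serum_1","F","serum"
"F_serum_2","F","serum"
"F_serum_3","F","serum"
"F_serum_4","F","serum"
"F_liver_1","F","liver"
"F_liver_2","F","liver"
"F_liver_3","F","liver"
"F_liver_4","F","liver"
"F_vastus_muscle_1","F","vastus muscle"
"F_vastus_muscle_2","F","vastus muscle"
"F_vastus_muscle_3","F","vastus muscle"
"F_vastus_muscle_4","F","vastus muscle"
"M_serum_1","M","serum"
"M_serum_2","M","serum"
"M_serum_3","M","serum"
"M_serum_4","M","serum"
"M_liver_1","M","liver"
"M_liver_2","M","liver"
"M_liver_3","M","liver"
"M_liver_4","M","liver"
"M_vastus_muscle_1","M","vastus muscle"
"M_vastus_muscle_2","M","vastus muscle"
"M_vastus_muscle_3","M","vastus muscle"
"M_vastus_muscle_4","M","vastus muscle"
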