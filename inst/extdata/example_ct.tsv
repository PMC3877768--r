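sample_id	condition	gene	is_reference_gene	ct
s1	mock	miR21	FALSE	25
s2	mock	miR30	FALSE	24
s3	mock	18s	TRUE	15
s4	mock	18s	TRUE	15
s5	antimir21	miR21	FALSE	25.152
s6	antimir21	miR30	FALSE	26.3219
s7	antimir21	18s	TRUE	15
s8	antimir21	18s	TRUE	15
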