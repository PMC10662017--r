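set_alpha	synthetic example set	gene_1	gene_2	gene_3	gene_4	gene_5	gene_6	gene_7	gene_8
set_beta	synthetic example set	gene_21	gene_22	gene_23	gene_24	gene_25
set_gamma	synthetic example set	gene_50	gene_60	gene_70	gene_80
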