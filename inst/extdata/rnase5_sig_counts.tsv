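gene_id	protein_yield	protein_pct	fertility	fat_yield	fat_pct	milk_yield
ACTA2	7	0	5	6	2	6
ACTN2	2	0	0	1	2	2
FBLN1	4	10	5	0	0	3
FSLP3	3	9	1	2	0	0
FST	2	8	0	1	4	1
HIF1	1	1	2	0	0	3
PLEC2	16	15	3	15	16	16
RFX7	2	2	0	0	1	0
RNASE4/5	5	0	0	1	0	4
RPL22L1	4	5	2	1	0	1
SP140	2	7	0	0	2	4
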