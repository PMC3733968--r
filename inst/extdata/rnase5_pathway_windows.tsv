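gene_id	chrom	win_start	win_stop	n_snps
ACTA2	26	10578865	11592811	26
ACTN2	28	7393500	8441168	16
FBLN1	5	122206254	123286509	22
FSLP3	7	41906484	42911309	20
FST	20	26797134	27802564	13
HIF1	10	75457880	76502552	17
PLEC2	14	190799	1212951	16
RFX7	10	54530392	55670964	25
RNASE4/5	10	25298775	26315348	23
RPL22L1	1	98326431	99330809	17
SP140	2	121890759	122935785	16
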