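# Published CYP2D6 structural-variant / CNV comparison for the 13 samples.
# cn_* columns are the printed copy-number triplet (CYP2D6/CYP2D7/hybrid).
form	sample	cn_2d6	cn_2d7	cn_hybrid	hybrid	diplotype	phenotype	activity_score	diplotype_concordance	phenotype_concordance
hybrid	Sample 10	2	2	1	CYP2D6-2D7	*4/*41,*68	PM	0.5	yes	yes
duplication	Sample 3	3	2	0	absence	*2 x 2/*41	NM	2.25	yes	yes
duplication	Sample 11	3	2	0	absence	*1/*4 x 2	IM	1.0	yes	yes
deletion	Sample 1	1	2	0	absence	*5/*17	PM	0.5	yes	yes
deletion-duplication	Sample 4	3	2	0	absence	*2 x 2/*5	IM	1.0	no	yes
composite	Sample 13	3	2	1	CYP2D6-2D7	*1 x 2/*4,*68	NM	2.0	yes	yes
snv-indel	Sample 12	2	2	0	absence	*1/*41	NM	1.25	yes	yes
snv-indel	Sample 9	2	2	0	absence	*29/*43	IM	1.0	yes	yes
snv-indel	Sample 8	2	2	0	absence	*1/*10	NM	1.25	yes	yes
snv-indel	Sample 7	2	2	0	absence	*4/*6	PM	0	yes	yes
snv-indel	Sample 6	2	2	0	absence	*1/*41	NM	1.25	yes	yes
snv-indel	Sample 5	2	2	0	absence	*9/*41	PM	0.5	yes	yes
snv-indel	Sample 2	2	2	0	absence	*2/*2	NM	2.0	yes	yes
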