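# Short-read call set for the 13-sample comparison cohort, transcribed from
# the published per-gene tables and the promoter-marker depth details.
# markers: semicolon-separated auxiliary haplotype-marker genotypes
#   (star=het|hom_ref|hom_alt|nocall); '-' when none reported.
sample	gene	diplotype	phenotype	markers
Sample 1	CYP2D6	*5/*17	PM	-
Sample 1	UGT1A1	*36/*60	NM	-
Sample 1	NAT2	*4/*5,*12	IA	-
Sample 2	CYP2D6	*2/*2	NM	-
Sample 2	UGT1A1	*1/*28	IM	*60=het;*93=het
Sample 2	NAT2	*4/*4	RA	-
Sample 3	CYP2D6	*2 x 2/*41	NM	-
Sample 3	UGT1A1	*1/*60	IM	-
Sample 3	NAT2	*6/*13	IA	-
Sample 4	CYP2D6	*2/*2	IM	-
Sample 4	UGT1A1	*1/*1	NM	-
Sample 4	NAT2	*5,*12,*13/*6,*11	IA	-
Sample 5	CYP2D6	*9/*41	PM	-
Sample 5	UGT1A1	*1/*28	IM	*60=het;*93=het
Sample 5	NAT2	*5,*11,*12/*5,*11,*12	SA	-
Sample 6	CYP2D6	*1/*41	NM	-
Sample 6	UGT1A1	*1/*1	NM	-
Sample 6	NAT2	*4/*5,*11,*12	IA	-
Sample 7	CYP2D6	*4/*6	PM	-
Sample 7	UGT1A1	*28/*28	PM	-
Sample 7	NAT2	*4/*6,*13	IA	-
Sample 8	CYP2D6	*1/*10	NM	-
Sample 8	UGT1A1	*1/*28	IM	-
Sample 8	NAT2	*5,*11,*12/*5,*12	SA	-
Sample 9	CYP2D6	*29/*43	IM	-
Sample 9	UGT1A1	*36/*37	IM	-
Sample 9	NAT2	*5,*12/*11	SA	-
Sample 10	CYP2D6	*4/*41,*68	PM	-
Sample 10	UGT1A1	*1/*28	IM	-
Sample 10	NAT2	*4/*5,*11,*12	IA	-
Sample 11	CYP2D6	*1/*4 x 2	IM	-
Sample 11	UGT1A1	*1/*28	IM	-
Sample 11	NAT2	*6/*13	IA	-
Sample 12	CYP2D6	*1/*41	NM	-
Sample 12	UGT1A1	*1/*28	IM	*60=het;*93=het
Sample 12	NAT2	*5,*11,*12/*5,*11,*12	SA	-
Sample 13	CYP2D6	*1 x 2/*4,*68	NM	-
Sample 13	UGT1A1	*28/*28	PM	-
Sample 13	NAT2	*6,*13/*6,*13	SA	-
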