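# Star-allele definitions.
# defining_variants: comma-separated var_ids ('-' for none: reference,
#   repeat-defined, deletion and hybrid alleles).
# core_variant: the single variant used for inter-allele distance
#   computations ('-' if the allele has no core SNV).
# ta_repeats: promoter TA unit count for repeat-defined alleles (NA else).
# activity: per-copy activity value; 'unknown' when no value is assigned.
# allele_type: one of reference, snv, repeat, deletion, hybrid.
gene	star	defining_variants	core_variant	ta_repeats	activity	function_class	acetylation_class	allele_type
NAT2	*4	-	-	NA	1	normal	rapid	reference
NAT2	*5	c.341T>C	c.341T>C	NA	0	none	slow	snv
NAT2	*6	c.590G>A	c.590G>A	NA	0	none	slow	snv
NAT2	*7	c.857G>A	c.857G>A	NA	0	none	slow	snv
NAT2	*11	c.481C>T	c.481C>T	NA	unknown	unknown	unclassified	snv
NAT2	*12	c.803A>G	c.803A>G	NA	1	normal	rapid	snv
NAT2	*13	c.282C>T	c.282C>T	NA	1	normal	rapid	snv
NAT2	*14	c.191G>A	c.191G>A	NA	0	none	slow	snv
UGT1A1	*1	-	-	6	1	normal	-	repeat
UGT1A1	*28	-	-	7	0.3	decreased	-	repeat
UGT1A1	*36	-	-	5	1	normal	-	repeat
UGT1A1	*37	-	-	8	0.3	decreased	-	repeat
UGT1A1	*60	g.2000T>G	g.2000T>G	NA	0.7	decreased	-	snv
UGT1A1	*93	g.2200G>A	g.2200G>A	NA	unknown	unknown	-	snv
CYP2D6	*1	-	-	NA	1	normal	-	reference
CYP2D6	*2	g.3000C>T	g.3000C>T	NA	1	normal	-	snv
CYP2D6	*3	g.3045G>A	g.3045G>A	NA	0	none	-	snv
CYP2D6	*4	g.3090A>G	g.3090A>G	NA	0	none	-	snv
CYP2D6	*5	-	-	NA	0	none	-	deletion
CYP2D6	*6	g.3135C>A	g.3135C>A	NA	0	none	-	snv
CYP2D6	*9	g.3180G>T	g.3180G>T	NA	0.25	decreased	-	snv
CYP2D6	*10	g.3225C>T	g.3225C>T	NA	0.25	decreased	-	snv
CYP2D6	*17	g.3270T>C	g.3270T>C	NA	0.5	decreased	-	snv
CYP2D6	*28	g.3315G>C	g.3315G>C	NA	unknown	unknown	-	snv
CYP2D6	*29	g.3360A>T	g.3360A>T	NA	0.5	decreased	-	snv
CYP2D6	*33	g.3405C>G	g.3405C>G	NA	unknown	unknown	-	snv
CYP2D6	*34	g.3450T>A	g.3450T>A	NA	1	normal	-	snv
CYP2D6	*35	g.3495G>A	g.3495G>A	NA	1	normal	-	snv
CYP2D6	*41	g.3540C>T	g.3540C>T	NA	0.25	decreased	-	snv
CYP2D6	*43	g.3585A>C	g.3585A>C	NA	0.5	decreased	-	snv
CYP2D6	*45	g.3630G>A	g.3630G>A	NA	unknown	unknown	-	snv
CYP2D6	*53	g.3675T>G	g.3675T>G	NA	unknown	unknown	-	snv
CYP2D6	*71	g.3720C>A	g.3720C>A	NA	unknown	unknown	-	snv
CYP2D6	*80	g.3765A>G	g.3765A>G	NA	unknown	unknown	-	snv
CYP2D6	*68	-	-	NA	0	none	-	hybrid
CYP2D6	*36	-	-	NA	0	none	-	hybrid
CYP2D6	*4N	-	-	NA	0	none	-	hybrid
CYP2D6	*61	-	-	NA	0	none	-	hybrid
CYP2D6	*13	-	-	NA	0	none	-	hybrid
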