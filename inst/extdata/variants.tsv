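# Variant definitions for the three synthetic loci.
# coord is 1-based in the gene's coordinate frame (cDNA for NAT2, position in
# the synthetic locus window otherwise).
gene	var_id	coord	ref	alt
NAT2	c.191G>A	191	G	A
NAT2	c.282C>T	282	C	T
NAT2	c.341T>C	341	T	C
NAT2	c.481C>T	481	C	T
NAT2	c.590G>A	590	G	A
NAT2	c.803A>G	803	A	G
NAT2	c.857G>A	857	G	A
UGT1A1	g.2000T>G	2000	T	G
UGT1A1	g.2200G>A	2200	G	A
CYP2D6	g.3000C>T	3000	C	T
CYP2D6	g.3045G>A	3045	G	A
CYP2D6	g.3090A>G	3090	A	G
CYP2D6	g.3135C>A	3135	C	A
CYP2D6	g.3180G>T	3180	G	T
CYP2D6	g.3225C>T	3225	C	T
CYP2D6	g.3270T>C	3270	T	C
CYP2D6	g.3315G>C	3315	G	C
CYP2D6	g.3360A>T	3360	A	T
CYP2D6	g.3405C>G	3405	C	G
CYP2D6	g.3450T>A	3450	T	A
CYP2D6	g.3495G>A	3495	G	A
CYP2D6	g.3540C>T	3540	C	T
CYP2D6	g.3585A>C	3585	A	C
CYP2D6	g.3630G>A	3630	G	A
CYP2D6	g.3675T>G	3675	T	G
CYP2D6	g.3720C>A	3720	C	A
CYP2D6	g.3765A>G	3765	A	G
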