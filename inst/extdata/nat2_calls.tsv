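# Published NAT2 phasing comparison for the 13 samples: statistical phasing
# after short reads vs direct read-backed phasing after long reads, with the
# acetylator status each method reported (stored verbatim, including the two
# printed statuses that the slow-haplotype count rule does not reproduce).
form	sample	diplotype_srs	status_srs	diplotype_lrs	status_lrs	concordance
non-ambiguous	Sample 1	*4/*5,*12	IA	*4/*5,*12	IA	yes
non-ambiguous	Sample 2	*4/*4	RA	*4/*4	RA	yes
non-ambiguous	Sample 3	*6/*13	IA	*4/*6,*13	IA	no
non-ambiguous	Sample 5	*5,*11,*12/*5,*11,*12	SA	*5,*11,*12/*5,*11,*12	SA	yes
non-ambiguous	Sample 6	*4/*5,*11,*12	IA	*4/*5,*11,*12	IA	yes
non-ambiguous	Sample 7	*4/*6,*13	IA	*4/*6,*13	IA	yes
non-ambiguous	Sample 8	*5,*11,*12/*5,*12	SA	*5,*11,*12/*5,*12	SA	yes
non-ambiguous	Sample 9	*5,*12/*11	SA	*12/*5,*11	SA	no
non-ambiguous	Sample 10	*4/*5,*11,*12	IA	*12/*5,*11	IA	no
non-ambiguous	Sample 11	*6/*13	IA	*12/6,*13,*12	IA	no
non-ambiguous	Sample 12	*5,*11,*12/*5,*11,*12	SA	*5,*11,*12/*5,*11,*12	SA	yes
non-ambiguous	Sample 13	*6,*13/*6,*13	SA	*6,*13/*6,*13	SA	yes
ambiguous	Sample 4	*5,*12,*13/*6,*11	IA	*6,*13,*12/*5,*11	IA	no
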