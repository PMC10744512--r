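# Population haplotype frequencies used by statistical phasing to join phase
# blocks. Haplotypes are canonical comma-separated star sets. The table is a
# deliberate emulation of a frequency-driven statistical phaser: it is
# calibrated so that the frequency-maximising join reproduces the behaviour
# of such phasers on block-ambiguous NAT2 genotypes (favouring the common
# linked *5,*11,*12 haplotype over rare trans configurations, and favouring
# trans *6/*13 over the rarer *4 + *6,*13 configuration). Haplotypes absent
# from the table receive a floor frequency of 1e-4.
gene	haplotype	freq
NAT2	*4	0.25
NAT2	*5,*11,*12	0.22
NAT2	*6	0.12
NAT2	*13	0.12
NAT2	*12	0.04
NAT2	*6,*13	0.04
NAT2	*5	0.03
NAT2	*5,*12	0.02
NAT2	*6,*12	0.02
NAT2	*12,*13	0.02
NAT2	*5,*11	0.01
NAT2	*11	0.01
NAT2	*11,*12	0.01
NAT2	*7	0.01
NAT2	*7,*13	0.01
NAT2	*14	0.005
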