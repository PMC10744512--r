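# Published UGT1A1 promoter TA-repeat comparison for the 13 samples.
# ta columns give the repeat diplotype (identical between methods).
sample	diplotype	phenotype	activity_score	ta	concordance
Sample 1	*36/*60	NM	2.125	TA5/TA6	yes
Sample 2	*1/*28	IM	1.3	TA6/TA7	yes
Sample 3	*1/*60	IM	1.7	TA6/TA6	yes
Sample 4	*1/*1	NM	2	TA6/TA6	yes
Sample 5	*1/*28	IM	1.3	TA6/TA7	yes
Sample 6	*1/*1	NM	2	TA6/TA6	yes
Sample 7	*28/*28	PM	0.6	TA7/TA7	yes
Sample 8	*1/*28	IM	1.3	TA6/TA7	yes
Sample 9	*36/*37	IM	1.3	TA5/TA8	yes
Sample 10	*1/*28	IM	1.3	TA6/TA7	yes
Sample 11	*1/*28	IM	1.3	TA6/TA7	yes
Sample 12	*1/*28	IM	1.3	TA6/TA7	yes
Sample 13	*28/*28	PM	0.6	TA7/TA7	yes
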