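# TRUST-style clonotype report
# fractional counts are read-assignment estimates
sample	count	CDR3aa	CDR3nt	Vgene	Jgene	chain
S1	11.6	CASSLAPGATNEKLFF	TGTGCCAGCAGCTTGGCC	TRBV7-9	TRBJ1-4	TRB
S1	3.2	CAVRDSNYQLIW	TGTGCTGTGAGAGATAGC	TRAV3	TRAJ33	TRA
S1	2.0	CAVRDSNYQLIW	TGTGCTGTGAGAGATAGC	TRAV3	TRAJ33	TRA
S2	5.4	CASSLAPGATNEKLFF	TGTGCCAGCAGCTTGGCC	TRBV7-9	TRBJ1-4	TRB
S2	0.3	CASSFDWGGDTQYF	TGTGCCAGCAGTTTTGAC	TRBV5-1	TRBJ2-3	TRB
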