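repertoire_id	locus	junction_aa	junction	v_call	j_call	duplicate_count
S1	TRB	CASSLAPGATNEKLFF	TGTGCCAGCAGCTTGGCC	TRBV7-9	TRBJ1-4	12
S1	TRA	CAVRDSNYQLIW	TGTGCTGTGAGAGATAGC	TRAV3	TRAJ33	3
S2	TRB	CASSLAPGATNEKLFF	TGTGCCAGCAGCTTGGCC	TRBV7-9	TRBJ1-4	5
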