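sample_id	patient_id	location	timepoint	sample_type	subtype	outcome
S1	P01	L1	1	biopsy	proliferative	regressive
S2	P01	L2	1	biopsy	proliferative	progressive/persistent
S3	P02	L1	1	brush		unknown
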