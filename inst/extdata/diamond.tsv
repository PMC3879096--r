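reaction_id	equation	reversible	lb	ub	knockable
R1	-> A	0	0	Inf	1
R2	A -> B	0	0	Inf	1
R3	A -> B	0	0	Inf	1
R4	B ->	0	0	Inf	1
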