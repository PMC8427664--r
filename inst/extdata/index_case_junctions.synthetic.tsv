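junction_id	chrom_a	pos_a	side_a	chrom_b	pos_b	side_b	inserted_seq
J1	chr6	14000000	left_of_cut	chr6	109000000	left_of_cut	G
J2	chr6	14000001	right_of_cut	chr6	155210000	left_of_cut	
J4	chr6	109000001	right_of_cut	chr6	156240700	left_of_cut	
J5	chr6	155210001	right_of_cut	chr6	157240708	right_of_cut	
J3	chr6	158240700	left_of_cut	chr6	157240695	left_of_cut	TTTGAAG
J6	chr6	156240701	right_of_cut	chr6	158240701	right_of_cut	
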