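receptor	ligand	pose_id	score
fragment1	LEC2	frag1_LEC2	-670.7
fragment1	WUS	frag1_WUS	-624.5
fragment1	LEC1	frag1_LEC1	-722.1
fragment1	AGLI5-fragment1	frag1_AGLI5f1	-754.3
fragment1	AGLI5-fragment2	frag1_AGLI5f2	-464.0
fragment2	LEC2	frag2_LEC2	-554.0
fragment2	WUS	frag2_WUS	-600.9
fragment2	LEC1	frag2_LEC1	-607.1
fragment2	AGLI5-fragment1	frag2_AGLI5f1	-795.3
fragment2	AGLI5-fragment2	frag2_AGLI5f2	-506.2
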