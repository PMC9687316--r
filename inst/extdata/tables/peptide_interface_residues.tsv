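peptide	pose	fragment	residues
P1	dock16	fragment1	ILE210, TYR211, LEU246, GLY247, TYR249, LYS251, GLU253, LYS254, ARG257, ALA258, LEU261, ALA262, PHE275
P2	dock89	fragment1	ARG216, TYR223, ASP250, LYS251, GLU252, GLU253, LYS254, ARG257, PHE275, PRO276
P2	dock10	fragment1	ALA225, TYR245, LEU246, GLY247, GLY248, TYR249, GLU253, LYS254, ARG257, ALA258, TYR259, LEU261
P3	dock49	fragment2	VAL316, THR317, TRP325, GLN326, ALA327, ARG328, GLN346, GLU347, ALA350, GLU351, TYR353, ASP354
P4	dock96	fragment1	ARG222, GLY248, TYR249, ASP250, LYS251, LYS254, ALA255, ARG257
P5	dock57	fragment1	TYR249, ASP250, LYS251, GLU253, LYS254, ARG257, ALA258, LEU261
P6	dock2	fragment1	TYR249, ASP250, LYS251, LYS254, ARG257, ALA258, LEU261, LEU264, LYS265, GLY268
P7	dock30	fragment2	THR317, TRP325, GLU351, ASP354, VAL316, GLN346, TYR353, ARG328, ALA349, ILE358, ALA350, ALA357
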