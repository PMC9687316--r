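table	complex	dG_kcal_mol	Kd_M
protein	fragment1_LEC2_dock46	-11.2	5.7e-9
protein	fragment1_WUS_dock45	-10.6	1.7e-8
protein	fragment1_LEC1_dock3	-12.3	8.8e-10
protein	fragment1_AGLI5f1_dock86	-11.1	7.7e-9
protein	fragment1_AGLI5f2_dock28	-10.1	4.0e-8
protein	fragment2_LEC2_dock28	-8.6	4.8e-7
protein	fragment2_WUS_dock7	-9.5	1.0e-7
protein	fragment2_LEC1_dock33	-8.7	4.1e-7
protein	fragment2_AGLI5f1_dock61	-9.7	7.5e-8
protein	fragment2_AGLI5f2_dock2	-8.5	5.9e-7
peptide	P1_dock16	-7.1	6.0e-6
peptide	P2_dock89	-7.7	2.1e-6
peptide	P2_dock10	-7.2	5.4e-6
peptide	P3_dock49	-8.0	1.5e-6
peptide	P4_dock96	-8.1	1.1e-6
peptide	P5_dock57	-7.7	2.4e-6
peptide	P6_dock2	-6.7	1.2e-5
peptide	P7_dock30	-4.9	2.4e-4
md_cluster	P2_dock10_cluster	-6.9	9.1e-6
md_cluster	P4_cluster	-6.1	3.5e-5
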