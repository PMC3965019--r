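# Synthetic approximation of the consensus library of favorable RNA
# backbone suite conformers: 54 combinations of canonical rotameric
# torsion states. Row 1a is set to standard A-form torsions. These are
# NOT the published consensus means; replace via the path argument of
# suiteConformerTable() to use a different table.
name	deltaMinus1	epsilonMinus1	zetaMinus1	alpha	beta	gamma	delta
1a	82	-153	-71	-68	178	54	82
s02	147	-153	-71	-68	178	54	84
s03	84	-153	-71	-68	178	54	147
s04	147	-153	-71	-68	178	54	147
s05	84	-153	-71	-68	178	178	84
s06	147	-153	-71	-68	178	178	84
s07	84	-153	-71	-68	178	178	147
s08	147	-153	-71	-68	178	178	147
s09	84	-153	-71	-68	178	-64	84
s10	147	-153	-71	-68	178	-64	84
s11	84	-153	-71	-68	178	-64	147
s12	147	-153	-71	-68	178	-64	147
s13	84	-153	-71	65	178	54	84
s14	147	-153	-71	65	178	54	84
s15	84	-153	-71	65	178	54	147
s16	147	-153	-71	65	178	54	147
s17	84	-153	-71	65	178	178	84
s18	147	-153	-71	65	178	178	84
s19	84	-153	-71	65	178	178	147
s20	147	-153	-71	65	178	178	147
s21	84	-153	-71	65	178	-64	84
s22	147	-153	-71	65	178	-64	84
s23	84	-153	-71	65	178	-64	147
s24	147	-153	-71	65	178	-64	147
s25	84	-153	-71	165	178	54	84
s26	147	-153	-71	165	178	54	84
s27	84	-153	-71	165	178	54	147
s28	147	-153	-71	165	178	54	147
s29	84	-153	-71	165	178	178	84
s30	147	-153	-71	165	178	178	84
s31	84	-153	-71	165	178	178	147
s32	147	-153	-71	165	178	178	147
s33	84	-153	-71	165	178	-64	84
s34	147	-153	-71	165	178	-64	84
s35	84	-153	-71	165	178	-64	147
s36	147	-153	-71	165	178	-64	147
s37	84	-98	65	-68	-125	54	84
s38	147	-98	65	-68	-125	54	84
s39	84	-98	65	-68	-125	54	147
s40	147	-98	65	-68	-125	54	147
s41	84	-98	65	-68	-125	178	84
s42	147	-98	65	-68	-125	178	84
s43	84	-98	65	-68	-125	178	147
s44	147	-98	65	-68	-125	178	147
s45	84	-98	65	-68	-125	-64	84
s46	147	-98	65	-68	-125	-64	84
s47	84	-98	65	-68	-125	-64	147
s48	147	-98	65	-68	-125	-64	147
s49	84	-153	175	165	178	54	84
s50	147	-153	175	165	178	54	84
s51	84	-153	175	165	178	54	147
s52	147	-153	175	165	178	54	147
s53	84	-98	-71	-68	100	54	84
s54	84	-98	-71	-68	70	54	84
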