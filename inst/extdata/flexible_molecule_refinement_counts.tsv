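# Published conformer counts for a three-step refinement (cheap single
# point -> optimization + frequencies -> high-level single point) of eight
# flexible molecules, with the reported integer-percent retention rate.
molecule	starting	step1	step2	step3	reported_retention_pct
Diethylphthalate	156	151	35	35	22
Guaiol	118	109	34	34	29
PenicillinV	136	71	12	12	9
Permethrin	304	304	101	101	33
Rivaroxaban	110	110	30	30	27
Sitagliptin	428	343	142	142	33
Tamiflu	836	527	100	99	12
AscorbicAcid	134	68	45	45	33
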