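chain_label	residue_number	residue_name	atom_number	atom_type	interacting_partners
A	1	GLN	3	C	3862,4094,4098
A	1	GLN	8	C	4098,4229
A	2	ALA	11	C	4097,4098
A	2	ALA	13	C	4200
A	5	HIE	34	C	3838,3860,3861
A	7	VAL	50	C	3838,4222,4224
A	56	GLN	427	C	4221
A	56	GLN	428	O	4221
A	56	GLN	431	C	
A	59	THR	456	C	4199
A	60	GLU	458	N	4199
A	60	GLU	459	C	4199,4176
A	60	GLU	461	C	4199
A	62	ILE	474	C	4176,4199,4200
A	62	ILE	475	C	4194
A	62	ILE	477	C	
A	62	ILE	478	O	4194
A	80	LEU	610	C	4073
B	481	VAL	3838	C	34,50
B	484	TRP	3860	C	34
B	484	TRP	3861	C	34
B	484	TRP	3862	C	3
B	511	ARG	4073	C	610
B	512	LEU	4080	C	
B	514	GLN	4094	C	3
B	514	GLN	4097	C	11
B	514	GLN	4098	O	3,8,11
B	523	TYR	4171	O	
B	524	MET	4176	S	459,474
B	526	MET	4194	C	475,478
B	527	VAL	4196	N	
B	527	VAL	4199	C	456,458,459,461,474
B	527	VAL	4200	C	13,474
B	530	TRP	4221	C	427,428
B	530	TRP	4222	C	50
B	530	TRP	4224	C	50
B	530	TRP	4229	C	8
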