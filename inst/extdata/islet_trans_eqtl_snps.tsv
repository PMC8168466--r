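SNP	SNPChr	SNPPos	AssessedAllele	OtherAllele	Pvalue	GeneSymbol	Diabetes
rs4908921	1	6613858	T	C	0.00037375	PHF13	NA
rs4908922	1	6613888	T	A	0.00017326	PHF13	NA
rs16833237	1	151404898	C	T	9.25E-55	POGZ	NA
rs7934912	11	78218556	A	T	9.51E-26	GAB2	Yes
rs148861080	11	119116390	T	G	2.43E-08	C2CD2L	NA
rs78810435	15	73116649	A	G	8.12E-38	NEO1	NA
rs138994570	16	57470988	A	G	2.43E-06	POLR2C	NA
rs1049910	19	2430637	G	C	3.15E-24	LMNB2	Yes
rs7009	19	2754792	A	G	2.34E-19	SGTA	NA
rs13282	19	2754810	T	C	1.79E-05	SGTA	NA
rs577145	19	7624377	T	C	2.70E-18	XAB2	Yes
rs541600	19	7624391	C	T	3.14E-18	XAB2	Yes
rs60223674	20	34303255	A	C	1.11E-27	RBM39	Yes
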