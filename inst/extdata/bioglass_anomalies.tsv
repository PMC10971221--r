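comparison	experiment	accession	gene	name	tier
ctrl_vs_doped	SBA2	P02458	COL2A1	Collagen alpha-1(II) chain	ns
ctrl_vs_doped	SBA2	P19338	NCL	Nucleolin	ns
ctrl_vs_doped	SBA2	P14923	JUP	Junction plakoglobin	ns
ctrl_vs_doped	SBA2	Q9Y4Z0	LSM4	U6 snRNA-associated Sm-like protein LSm4	ns
ctrl_vs_doped	SBA3	P02656	APOC3	Apolipoprotein C-III	ns
ctrl_vs_doped	SBA3	P38571	LIPA	Lysosomal acid lipase/cholesteryl ester hydrolase	ns
ctrl_vs_doped	SBA3	Q9P2E9	RRBP1	Ribosome-binding protein 1	sig
ctrl_vs_doped	SBA3	P02765	AHSG	Alpha-2-HS-glycoprotein	ns
ctrl_vs_doped	SBA3	P49720	PSMB3	Proteasome subunit beta type-3	ns
ctrl_vs_doped	SBA3	P46940	IQGAP1	Ras GTPase-activating-like protein IQGAP1	ns
ctrl_vs_doped	SBA3	P59665	DEFA1	Neutrophil defensin 1	ns
ctrl_vs_doped	ST	P24821-4	TNC	Isoform 4 of Tenascin	ns
ctrl_vs_doped	ST	P26583	HMGB2	High mobility group protein B2	ns
ctrl_vs_doped	ST	P22234	PAICS	Multifunctional protein ADE2	marginal
ctrl_vs_doped	ST	P35555	FBN1	Fibrillin-1	sig
ctrl_vs_doped	ST	P24821	TNC	Tenascin	marginal
ctrl_vs_doped	ST	Q9P2E9	RRBP1	Ribosome-binding protein 1	sig
ctrl_vs_doped	ST	P13611	VCAN	Versican core protein	ns
plast_vs_doped	SBA2	P35908	KRT2	Keratin, Type II cytoskeletal 2 epidermal	sig
plast_vs_doped	SBA2	P35527	KRT9	Keratin, Type I cytoskeletal 9	sig
plast_vs_doped	SBA2	P04264	KRT1	Keratin, Type II cytoskeletal 1	sig
plast_vs_doped	SBA2	P13645	KRT10	Keratin, Type I cytoskeletal 10	sig
plast_vs_doped	SBA2	P60985	KRTDAP	Keratinocyte differentiation-associated protein	marginal
plast_vs_doped	SBA2	P12111	COL6A3	Collagen alpha-3(VI) chain	sig
plast_vs_doped	SBA2	P08493	MGP	Matrix Gla protein	ns
plast_vs_doped	SBA3	P00734	F2	Prothrombin	sig
plast_vs_doped	SBA3	P12111	COL6A3	Collagen alpha-3(VI) chain	marginal
plast_vs_doped	SBA3	P35908	KRT2	Keratin, Type II cytoskeletal 2 epidermal	sig
plast_vs_doped	SBA3	P35527	KRT9	Keratin, Type I cytoskeletal 9	sig
plast_vs_doped	SBA3	P13645	KRT10	Keratin, Type I cytoskeletal 10	sig
plast_vs_doped	SBA3	P04264	KRT1	Keratin, Type II cytoskeletal 1	sig
plast_vs_doped	ST	O94985	CLSTN1	Calsyntenin-1	sig
plast_vs_doped	ST	P22234	PAICS	Multifunctional protein ADE2	sig
plast_vs_doped	ST	P02545	LMNA	Prelamin-A/C	marginal
plast_vs_doped	ST	P04264	KRT1	Keratin, Type II cytoskeletal 1	sig
plast_vs_doped	ST	P35527	KRT9	Keratin, Type I cytoskeletal 9	sig
plast_vs_doped	ST	Q16363	LAMA4	Laminin subunit alpha-4	ns
plast_vs_doped	ST	P13645	KRT10	Keratin, Type I cytoskeletal 10	sig
plast_vs_doped	ST	P35908	KRT2	Keratin, Type II cytoskeletal 2 epidermal	sig
plast_vs_doped	ST	P00734	F2	Prothrombin	sig
plast_vs_doped	ST	P26022	PTX3	Pentraxin-related protein PTX3	marginal
plast_vs_doped	ST	P60985	KRTDAP	Keratinocyte differentiation-associated protein	sig
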