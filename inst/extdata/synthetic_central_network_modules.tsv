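module_id	name	compartment	pathway_group	substrates	products
M1	glucose uptake	extracellular	glycolysis	GLC_e	GLC_c
M2	glycolysis upper (Glc to G3P)	cytosol	glycolysis	GLC_c	G3P_c
M3	glycolysis mid (G3P to 3PG)	cytosol	glycolysis	G3P_c	PG3_c
M4	glycolysis lower (3PG to Pyr)	cytosol	glycolysis	PG3_c	PYR_c
M5	lactate production and export	cytosol	glycolysis	PYR_c	LAC_e
M6	pyruvate uptake	extracellular	glycolysis	PYR_e	PYR_c
M7	pyruvate mitochondrial import	mitochondrion	tca_upper	PYR_c	PYR_m
M8	pyruvate dehydrogenase	mitochondrion	tca_upper	PYR_m	ACCOA_m
M9	citrate synthase	mitochondrion	tca_upper	ACCOA_m;OAA_m	CIT_m
M10	TCA upper (Cit to 2-OG)	mitochondrion	tca_upper	CIT_m	AKG_m
M11	TCA lower (2-OG to Mal)	mitochondrion	tca_lower	AKG_m	MAL_m
M12	malate dehydrogenase (mito)	mitochondrion	tca_lower	MAL_m	OAA_m
M13	pyruvate carboxylase	mitochondrion	tca_lower	PYR_m	OAA_m
M14	malic enzyme	mitochondrion	tca_lower	MAL_m	PYR_m
M15	G3P to nucleotide synthesis	cytosol	nucleotide_branch	G3P_c	NUC_c
M16	3PG to serine synthesis	cytosol	serine_branch	PG3_c	SER_c
M17	citrate export and lipogenesis	cytosol	tca_upper	CIT_m	FA_c
M18	glycogen synthesis	cytosol	glycolysis	GLC_c	GLYCOGEN_c
M19	alanine transaminase	cytosol	glycolysis	PYR_c	ALA_c
M20	malate-aspartate shuttle, export arm	mitochondrion	asp_mal_shuttle	OAA_m	ASP_c
M21	malate-aspartate shuttle, return arm	cytosol	asp_mal_shuttle	ASP_c	MAL_m
M22	glutamine uptake	extracellular	glutaminolysis	GLN_e	GLN_c
M23	glutamine mitochondrial import	mitochondrion	glutaminolysis	GLN_c	GLN_m
M24	glutaminase	mitochondrion	glutaminolysis	GLN_m	GLU_m;NH4_m
M25	glutamine synthetase	cytosol	gln_glu_metabolism	GLU_c	GLN_c
M26	glutamate mitochondrial export	mitochondrion	gln_glu_metabolism	GLU_m	GLU_c
M27	glutamate to glutathione	cytosol	glutathione_metabolism	GLU_c;CYS_c;GLY_c	GSH_c
M28	glutamate to 2-OG	mitochondrion	gln_glu_metabolism	GLU_m	AKG_m
M29	glutamate uptake	extracellular	gln_glu_metabolism	GLU_e	GLU_c
M30	proline synthesis	cytosol	gln_glu_metabolism	GLU_c	PRO_c
M31	glutathione oxidation and conjugation	cytosol	glutathione_metabolism	GSH_c	GSSG_c
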