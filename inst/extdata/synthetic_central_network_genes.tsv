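module_id	gene
M1	SLC2A1
M1	SLC2A2
M1	SLC2A3
M1	SLC2A4
M1	SLC2A5
M1	SLC2A6
M1	SLC2A8
M1	SLC2A9
M1	SLC2A10
M1	SLC2A12
M1	SLC2A14
M2	HK1
M2	HK2
M2	HK3
M2	GCK
M2	HKDC1
M2	GPI
M2	PFKL
M2	PFKM
M2	PFKP
M2	PFKFB1
M2	PFKFB2
M2	PFKFB3
M2	PFKFB4
M2	FBP1
M2	FBP2
M2	ALDOA
M2	ALDOB
M2	ALDOC
M2	TPI1
M3	GAPDH
M3	GAPDHS
M3	PGK1
M3	PGK2
M4	PGAM1
M4	PGAM2
M4	PGAM4
M4	BPGM
M4	ENO1
M4	ENO2
M4	ENO3
M4	PKM
M4	PKLR
M5	LDHA
M5	LDHB
M5	LDHC
M5	LDHAL6A
M5	LDHAL6B
M5	SLC16A1
M5	SLC16A3
M5	SLC16A7
M5	SLC16A8
M6	SLC5A8
M6	SLC5A12
M7	MPC1
M7	MPC2
M8	PDHA1
M8	PDHA2
M8	PDHB
M8	DLAT
M8	DLD
M8	PDHX
M8	PDK1
M8	PDK2
M8	PDK3
M8	PDK4
M8	PDP1
M8	PDP2
M9	CS
M10	ACO1
M10	ACO2
M10	IDH1
M10	IDH2
M10	IDH3A
M10	IDH3B
M10	IDH3G
M11	OGDH
M11	OGDHL
M11	DLST
M11	SUCLG1
M11	SUCLG2
M11	SUCLA2
M11	SDHA
M11	SDHB
M11	SDHC
M11	SDHD
M11	FH
M12	MDH2
M13	PC
M14	ME1
M14	ME2
M14	ME3
M15	TKT
M15	TKTL1
M15	TKTL2
M15	TALDO1
M15	RPIA
M15	RPE
M15	PRPS1
M15	PRPS2
M15	PRPS1L1
M15	PPAT
M15	GART
M15	PFAS
M15	PAICS
M15	ADSL
M15	ATIC
M15	IMPDH1
M15	IMPDH2
M15	GMPS
M15	ADSS1
M15	ADSS2
M15	CAD
M15	DHODH
M15	UMPS
M15	CTPS1
M15	CTPS2
M15	NME1
M15	NME2
M15	RRM1
M15	RRM2
M15	RRM2B
M15	TYMS
M15	DTYMK
M15	G6PD
M15	PGLS
M15	PGD
M15	HPRT1
M15	APRT
M15	TK1
M15	TK2
M15	DCK
M15	ADA
M15	ADK
M15	NT5E
M15	UPP1
M15	UCK1
M15	UCK2
M15	NME3
M15	NME4
M15	AK1
M15	AK2
M15	AK4
M16	PHGDH
M16	PSAT1
M16	PSPH
M16	SHMT1
M16	SHMT2
M17	SLC25A1
M17	ACLY
M17	ACACA
M17	ACACB
M17	FASN
M17	SCD
M17	ELOVL6
M17	ACSL1
M17	ACSL3
M17	ACSL4
M17	ACSS2
M17	MLYCD
M18	UGP2
M18	GYS1
M18	GYS2
M18	GBE1
M18	PGM1
M18	PGM2
M18	GSK3A
M18	GSK3B
M18	PYGL
M18	PYGM
M18	PYGB
M18	AGL
M19	GPT
M19	GPT2
M20	GOT2
M20	SLC25A12
M20	SLC25A13
M21	GOT1
M21	MDH1
M21	MDH1B
M21	SLC25A11
M22	SLC1A5
M22	SLC38A1
M22	SLC38A2
M22	SLC38A3
M22	SLC38A5
M22	SLC38A7
M22	SLC7A5
M22	SLC7A8
M22	SLC6A14
M22	SLC6A19
M23	SLC25A44
M23	VDAC1
M23	VDAC2
M23	VDAC3
M24	GLS
M24	GLS2
M25	GLUL
M26	SLC25A18
M26	SLC25A22
M27	GCLC
M27	GCLM
M27	GSS
M28	GLUD1
M28	GLUD2
M29	SLC1A1
M29	SLC1A2
M29	SLC1A3
M29	SLC1A6
M29	SLC1A7
M29	SLC7A11
M29	SLC3A2
M30	ALDH18A1
M30	PYCR1
M30	PYCR2
M30	PYCR3
M31	GPX1
M31	GPX2
M31	GPX3
M31	GPX4
M31	GPX7
M31	GPX8
M31	GSR
M31	GSTP1
M31	GSTM1
M31	GSTM2
M31	GSTM3
M31	GSTM4
M31	GSTA1
M31	GSTA2
M31	GSTA4
M31	GSTK1
M31	GSTO1
M31	GSTO2
M31	GSTT1
M31	GSTT2
M31	MGST1
M31	MGST2
M31	MGST3
M31	GGT1
M31	GGT5
M31	GGT6
M31	GGT7
M31	OPLAH
M31	CHAC1
M31	CHAC2
M31	ANPEP
M31	PRDX1
M31	PRDX2
M31	PRDX3
M31	PRDX4
M31	PRDX5
M31	PRDX6
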