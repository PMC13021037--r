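GO:0086001	cardiac muscle cell action potential	KCNQ1	SCN10A	HCN4	SCN5A	KCNE1	RYR2	ANK2	TRPM4	KCNH2	AKAP9
GO:0030001	metal ion transport	KCNQ1	SCN10A	HCN4	SCN5A	KCNE1	PCSK9	RYR2	ANK2	SLC22A5	TRPM4	KCNH2	AKAP9
GO:0014074	response to purine-containing compound	KCNQ1	HCN4	KCNE1	RYR2	TRPM4	AKAP9
GO:0048878	chemical homeostasis	KCNQ1	GDF2	LDLR	APOB	PCSK9	RYR2	ANK2	TRPM4	KCNH2
GO:0072359	circulatory system development	KCNQ1	GDF2	HCN4	LDLR	APOB	SCN5A	RYR2	ANK2	ENG
REAC:R-HSA-5576891	Cardiac conduction	KCNQ1	SCN10A	SCN5A	KCNE1	RYR2	KCNH2	AKAP9
REAC:R-HSA-5576890	Phase 3 - rapid repolarization	KCNQ1	KCNE1	KCNH2	AKAP9
REAC:R-HSA-397014	Muscle contraction	KCNQ1	SCN10A	SCN5A	KCNE1	RYR2	KCNH2	AKAP9
REAC:R-HSA-5576893	Phase 2 - plateau phase	KCNQ1	KCNE1	AKAP9
REAC:R-HSA-8964038	LDL clearance	LDLR	APOB	PCSK9
HP:0001695	Cardiac arrest	KCNQ1	SCN10A	HCN4	LDLR	APOB	SCN5A	KCNE1	PCSK9	RYR2	ANK2	TRPM4	KCNH2	AKAP9	TANGO2
HP:0001645	Sudden cardiac death	KCNQ1	SCN10A	HCN4	LDLR	APOB	SCN5A	KCNE1	PCSK9	RYR2	ANK2	KCNH2	AKAP9
HP:0005184	Prolonged QTc interval	KCNQ1	SCN10A	HCN4	SCN5A	KCNE1	ANK2	KCNH2	AKAP9	TANGO2
HP:0001663	Ventricular fibrillation	KCNQ1	SCN10A	HCN4	SCN5A	KCNE1	RYR2	TRPM4	KCNH2	AKAP9	TANGO2
HP:0001657	Prolonged QT interval	KCNQ1	SCN10A	HCN4	SCN5A	KCNE1	ANK2	TRPM4	KCNH2	AKAP9	TANGO2
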