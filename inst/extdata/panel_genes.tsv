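# Gene-to-panel map for the three Genomics England PanelApp panels used by
# the triage cascade: CA (cardiac arrhythmias), FH (familial
# hypercholesterolaemia), PAH (pulmonary arterial hypertension).
# Assignment is exclusive (one panel per gene); when building a map from raw
# PanelApp exports, apply CA > PAH > FH precedence to genes on several
# panels. This shipped file covers the 23 candidate genes of the default
# analysis; panel membership beyond the explicitly studied genes is a
# synthetic completion with canonical PAH panel genes, and a full
# user-supplied map can be passed in its place.
gene	panel
KCNQ1	CA
SCN10A	CA
HCN4	CA
SCN5A	CA
KCNE1	CA
RYR2	CA
ANK2	CA
TRPM4	CA
KCNH2	CA
AKAP9	CA
TANGO2	CA
CACNA1C	CA
SLC22A5	CA
SARS2	PAH
GDF2	PAH
ENG	PAH
BMPR2	PAH
ACVRL1	PAH
EIF2AK4	PAH
KCNK3	PAH
LDLR	FH
APOB	FH
PCSK9	FH
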