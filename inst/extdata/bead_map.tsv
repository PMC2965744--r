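# bead -> species/moiety mapping (tab-separated)
# an empty bead_name matches every bead of the residue
residue_name	bead_name	species	moiety
POPC	NC3	POPC	headgroup
POPC	PO4	POPC	headgroup
POPC	GL1	POPC	glycerol
POPC	GL2	POPC	glycerol
POPC	C1A	POPC	sn1_chain
POPC	C2A	POPC	sn1_chain
POPC	C3A	POPC	sn1_chain
POPC	C4A	POPC	sn1_chain
POPC	C1B	POPC	sn2_chain
POPC	D2B	POPC	sn2_chain
POPC	C3B	POPC	sn2_chain
POPC	C4B	POPC	sn2_chain
PPC	NC3	PPC	headgroup
PPC	PO4	PPC	headgroup
PPC	GL1	PPC	glycerol
PPC	C1A	PPC	sn1_chain
PPC	C2A	PPC	sn1_chain
PPC	C3A	PPC	sn1_chain
PPC	C4A	PPC	sn1_chain
CHOL	ROH	CHOL	sterol_ring
CHOL	R1	CHOL	sterol_ring
CHOL	R2	CHOL	sterol_ring
CHOL	R3	CHOL	sterol_ring
CHOL	R4	CHOL	sterol_ring
CHOL	R5	CHOL	sterol_ring
CHOL	C1	CHOL	sterol_tail
CHOL	C2	CHOL	sterol_tail
CE	EST	CE	ester
CE	R1	CE	sterol_ring
CE	R2	CE	sterol_ring
CE	R3	CE	sterol_ring
CE	R4	CE	sterol_ring
CE	R5	CE	sterol_ring
CE	C1	CE	sterol_tail
CE	C2	CE	sterol_tail
CE	O1	CE	oleate_chain
CE	O2	CE	oleate_chain
CE	O3	CE	oleate_chain
CE	O4	CE	oleate_chain
TG	ES1	TG	ester
TG	ES2	TG	ester
TG	ES3	TG	ester
TG	C1A	TG	sn1_chain
TG	C2A	TG	sn1_chain
TG	C3A	TG	sn1_chain
TG	C4A	TG	sn1_chain
TG	C1B	TG	sn2_chain
TG	C2B	TG	sn2_chain
TG	C3B	TG	sn2_chain
TG	C4B	TG	sn2_chain
TG	C1C	TG	sn3_chain
TG	C2C	TG	sn3_chain
TG	C3C	TG	sn3_chain
TG	C4C	TG	sn3_chain
POP	NC3	POPC	headgroup
POP	PO4	POPC	headgroup
POP	GL1	POPC	glycerol
POP	GL2	POPC	glycerol
POP	C1A	POPC	sn1_chain
POP	C2A	POPC	sn1_chain
POP	C3A	POPC	sn1_chain
POP	C4A	POPC	sn1_chain
POP	C1B	POPC	sn2_chain
POP	D2B	POPC	sn2_chain
POP	C3B	POPC	sn2_chain
POP	C4B	POPC	sn2_chain
CHL	ROH	CHOL	sterol_ring
CHL	R1	CHOL	sterol_ring
CHL	R2	CHOL	sterol_ring
CHL	R3	CHOL	sterol_ring
CHL	R4	CHOL	sterol_ring
CHL	R5	CHOL	sterol_ring
CHL	C1	CHOL	sterol_tail
CHL	C2	CHOL	sterol_tail
ALA	BB	PROTEIN	backbone
ARG	BB	PROTEIN	backbone
ASN	BB	PROTEIN	backbone
ASP	BB	PROTEIN	backbone
CYS	BB	PROTEIN	backbone
GLN	BB	PROTEIN	backbone
GLU	BB	PROTEIN	backbone
GLY	BB	PROTEIN	backbone
HIS	BB	PROTEIN	backbone
ILE	BB	PROTEIN	backbone
LEU	BB	PROTEIN	backbone
LYS	BB	PROTEIN	backbone
MET	BB	PROTEIN	backbone
PHE	BB	PROTEIN	backbone
PRO	BB	PROTEIN	backbone
SER	BB	PROTEIN	backbone
THR	BB	PROTEIN	backbone
TRP	BB	PROTEIN	backbone
TYR	BB	PROTEIN	backbone
VAL	BB	PROTEIN	backbone
ALA	NA	PROTEIN	sidechain
ARG	NA	PROTEIN	sidechain
ASN	NA	PROTEIN	sidechain
ASP	NA	PROTEIN	sidechain
CYS	NA	PROTEIN	sidechain
GLN	NA	PROTEIN	sidechain
GLU	NA	PROTEIN	sidechain
GLY	NA	PROTEIN	sidechain
HIS	NA	PROTEIN	sidechain
ILE	NA	PROTEIN	sidechain
LEU	NA	PROTEIN	sidechain
LYS	NA	PROTEIN	sidechain
MET	NA	PROTEIN	sidechain
PHE	NA	PROTEIN	sidechain
PRO	NA	PROTEIN	sidechain
SER	NA	PROTEIN	sidechain
THR	NA	PROTEIN	sidechain
TRP	NA	PROTEIN	sidechain
TYR	NA	PROTEIN	sidechain
VAL	NA	PROTEIN	sidechain
W	NA	WATER	other
SOL	NA	WATER	other
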