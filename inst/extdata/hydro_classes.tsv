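# residue hydrophobicity classes (editable)
residue_name	hydro_class
ALA	hydrophobic
ARG	hydrophilic
ASN	hydrophilic
ASP	hydrophilic
CYS	hydrophilic
GLN	hydrophilic
GLU	hydrophilic
GLY	hydrophilic
HIS	hydrophilic
ILE	hydrophobic
LEU	hydrophobic
LYS	hydrophilic
MET	hydrophobic
PHE	hydrophobic
PRO	hydrophilic
SER	hydrophilic
THR	hydrophilic
TRP	hydrophobic
TYR	hydrophilic
VAL	hydrophobic
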