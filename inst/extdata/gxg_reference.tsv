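# Reference accessible surface areas (Angstrom^2) of residue X in an
# extended Gly-X-Gly tripeptide, Miller et al. (1987) standard-state values.
# Used to normalise per-residue ASA to relative ASA (rASA). Version 1.
residue	ref_asa
ALA	113
ARG	241
ASN	158
ASP	151
CYS	140
GLN	189
GLU	183
GLY	85
HIS	194
ILE	182
LEU	180
LYS	211
MET	204
PHE	218
PRO	143
SER	122
THR	146
TRP	259
TYR	229
VAL	160
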