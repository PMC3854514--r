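# Per-residue property tables for the feature encoder. Version 1.
# SYNTHETIC STAND-IN: the numeric tables of the cited scales (residue volume,
# mean residue polarity, Klein charge classes, interhelical contact propensity,
# helix insertion free energy, amphiphilicity, turn propensity) are not
# redistributable here in full; this file carries plausible values of the same
# shape, with three anchors fixed exactly and asserted at load time:
#   volume  max = 237.2 (TYR);  contact max = 1.43 (CYS);  turn max = 2.7 (PRO)
# energy is the Hessa et al. (2005) apparent insertion free energy (published).
# charge: +1 positively charged (K/R/H), 0.5 neutral, 0 negatively charged (D/E).
# Replace via the property_table argument of loadPropertyTables().
residue	volume	polarity	charge	contact	energy	amphiphilicity	turn
ALA	88.6	-0.2	0.5	1.18	0.11	0.0	0.60
ARG	173.4	2.2	1	0.60	2.58	1.20	0.90
ASN	114.1	3.3	0.5	0.82	2.05	0.20	1.30
ASP	111.1	4.7	0	0.72	3.49	0.10	1.20
CYS	108.5	-2.8	0.5	1.43	-0.13	0.0	0.70
GLN	143.8	2.2	0.5	0.78	2.36	0.30	0.90
GLU	138.4	4.0	0	0.70	2.68	0.10	0.80
GLY	60.1	0.7	0.5	1.31	0.74	0.0	1.70
HIS	153.2	2.1	1	0.86	2.06	1.30	0.90
ILE	166.7	-3.1	0.5	0.95	-0.60	0.0	0.40
LEU	166.7	-3.4	0.5	0.98	-0.55	0.0	0.50
LYS	168.6	3.0	1	0.55	2.71	1.10	0.90
MET	162.9	-2.6	0.5	1.02	-0.10	0.10	0.60
PHE	189.9	-3.1	0.5	0.97	-0.32	0.50	0.60
PRO	112.7	-0.3	0.5	0.90	2.23	0.10	2.7
SER	89.0	0.9	0.5	1.12	0.84	0.10	1.10
THR	116.1	0.3	0.5	1.05	0.52	0.10	0.80
TRP	227.8	-2.9	0.5	0.85	0.30	1.90	0.80
TYR	237.2	-2.1	0.5	0.88	0.68	1.60	0.90
VAL	140.0	-2.4	0.5	1.00	-0.31	0.0	0.45
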