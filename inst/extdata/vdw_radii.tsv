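# van der Waals radii (Angstrom), NACCESS/Chothia convention, version 1.
# kind = element: default radius for that chemical element.
# kind = atom:    override keyed by PDB atom name (applied after element default).
# Edit or swap this file via the radii_table argument of readStructure().
kind	key	radius
element	C	1.87
element	N	1.65
element	O	1.40
element	S	1.85
element	P	1.80
element	SE	1.90
element	H	1.00
atom	C	1.76
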