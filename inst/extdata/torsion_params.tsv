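type	V1	V2	V3	g1	g2	g3	note
CCSS	0.8	0.0	6.0	0	180	0	C-C-S-S torsion: trans/gauche minima of comparable depth, trans lower by ~0.6 kJ/mol
CSSC	12.0	-31.0	7.13	0	180	0	S-S torsion: minima near +/-90 deg, high cis barrier, lower trans barrier
SP3	0.0	0.0	3.0	0	180	0	generic threefold barrier for remaining sp3 single bonds
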