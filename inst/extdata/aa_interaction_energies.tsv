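# Amino-acid / silicon nitride pore-wall interaction energies.
# minus_delta_e_ev is the printed positive magnitude -dE_AA in eV
# (equilibrium energy minus Morse asymptote); all 18 residues are
# attractive, so the signed interaction energy is the negative of
# this column.  MET and ILE have no entry: lookups of those codes
# are an error unless a substitute mapping is supplied.
code	minus_delta_e_ev	r_group_class
HIS	0.8913	positively_charged
ARG	2.4674	positively_charged
LYS	2.9291	positively_charged
ASP	2.8251	negatively_charged
GLU	2.7363	negatively_charged
ASN	1.2610	uncharged_polar
GLN	0.9411	uncharged_polar
SER	1.4538	uncharged_polar
THR	0.9887	uncharged_polar
TYR	1.2834	uncharged_polar
ALA	0.9876	nonpolar
VAL	0.9424	nonpolar
LEU	1.1341	nonpolar
PRO	1.0948	nonpolar
PHE	0.8881	nonpolar
TRP	1.0852	nonpolar
GLY	1.4880	nonpolar
CYS	1.4944	nonpolar
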