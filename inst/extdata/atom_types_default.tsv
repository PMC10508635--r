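element	context_flag	channel_index	radius_angstrom
C	aliphatic_hydrophobic	0	1.90
C	aliphatic_polar	1	1.90
C	aromatic_hydrophobic	2	1.90
C	aromatic_polar	3	1.90
N	donor	4	1.80
N	acceptor	5	1.80
N	donor_acceptor	6	1.80
N	plain	7	1.80
O	acceptor	8	1.70
O	donor_acceptor	9	1.70
S	any	10	2.00
P	any	11	2.10
F	any	12	1.50
CL	any	12	1.80
BR	any	12	1.90
I	any	12	2.00
NA	any	13	1.20
MG	any	13	1.20
K	any	13	1.20
CA	any	13	1.20
ZN	any	13	1.20
MN	any	13	1.20
FE	any	13	1.20
CU	any	13	1.20
CO	any	13	1.20
NI	any	13	1.20
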