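label	section	coulombic	vdw	total
T4.38	protomer	-0.01	-0.03	-0.04
P4.39	protomer	0.08	-0.02	0.06
R4.40	protomer	0.30	-0.31	-0.01
N4.41	protomer	-0.32	-1.06	-1.38
I4.44	protomer	-0.02	-3.56	-3.58
I4.45	protomer	0.09	-1.22	-1.13
V4.47	protomer	-0.06	-0.24	-0.31
C4.48	protomer	0.11	-1.49	-1.38
W4.50	protomer	0.03	-0.02	0.01
I4.51	protomer	0.18	-2.77	-2.58
L4.52	protomer	0.03	-0.11	-0.08
S4.54	protomer	0.03	-0.06	-0.03
A4.55	protomer	0.21	-2.11	-1.90
I4.56	protomer	0.11	-2.42	-2.32
G4.57	protomer	-0.03	0.00	-0.04
P4.59	protomer	0.01	-0.07	-0.06
protomer_subtotal	subtotal	0.74	-15.50	-14.76
CHOL_A_vs_B	cholesterol	0.07	-2.52	-2.44
CHOL_B_vs_A	cholesterol	0.10	-2.49	-2.39
chol_subtotal	subtotal	0.17	-5.01	-4.83
grand_total	total	0.91	-20.51	-19.59
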