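# Per-residue scalar descriptors.
# kd: Kyte-Doolittle hydropathy; fp: Fauchere-Pliska hydrophobic index;
# polarity: Grantham; charge: formal side-chain charge at pH 7 (His 0.5);
# volume: residue volume (A^3); pi: isoelectric point;
# helix / sheet: Chou-Fasman conformational propensities.
aa	kd	fp	polarity	charge	volume	pi	helix	sheet
A	1.8	0.31	8.1	0	88.6	6.00	1.42	0.83
R	-4.5	-1.01	10.5	1	173.4	10.76	0.98	0.93
N	-3.5	-0.60	11.6	0	114.1	5.41	0.67	0.89
D	-3.5	-0.77	13.0	-1	111.1	2.77	1.01	0.54
C	2.5	1.54	5.5	0	108.5	5.07	0.70	1.19
Q	-3.5	-0.22	10.5	0	143.8	5.65	1.11	1.10
E	-3.5	-0.64	12.3	-1	138.4	3.22	1.51	0.37
G	-0.4	0.00	9.0	0	60.1	5.97	0.57	0.75
H	-3.2	0.13	10.4	0.5	153.2	7.59	1.00	0.87
I	4.5	1.80	5.2	0	166.7	6.02	1.08	1.60
L	3.8	1.70	4.9	0	166.7	5.98	1.21	1.30
K	-3.9	-0.99	11.3	1	168.6	9.74	1.16	0.74
M	1.9	1.23	5.7	0	162.9	5.74	1.45	1.05
F	2.8	1.79	5.2	0	189.9	5.48	1.13	1.38
P	-1.6	0.72	8.0	0	112.7	6.30	0.57	0.55
S	-0.8	-0.04	9.2	0	89.0	5.68	0.77	0.75
T	-0.7	0.26	8.6	0	116.1	5.60	0.83	1.19
W	-0.9	2.25	5.4	0	227.8	5.89	1.08	1.37
Y	-1.3	0.96	6.2	0	193.6	5.66	0.69	1.47
V	4.2	1.22	5.9	0	140.0	5.96	1.06	1.70
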