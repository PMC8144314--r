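gene_id	series	probe_id	adj_p	p	log_fc
AHI1	pbmc	221569_at	1.57E-02	1.74E-03	-5.05E-01
AHI1	pbtc	244699_at	3.92E-01	7.69E-02	8.27E-02
CD58	pbmc	222061_at	1.17E-01	2.71E-02	-3.00E-01
CD58	pbtc	222061_at	1.44E-01	1.13E-02	-1.67E-01
CDSN	pbmc	206193_s_at	1.85E-01	5.34E-02	-1.09E-01
CDSN	pbtc	206193_s_at	6.61E-01	2.46E-01	3.94E-02
CLEC16A	pbmc	231221_at	4.83E-01	2.69E-01	-7.93E-02
CLEC16A	pbtc	212786_at	4.33E-01	9.39E-02	-1.06E-01
COL11A2	pbmc	216993_s_at	1.91E-01	5.62E-02	1.32E-01
COL11A2	pbtc	213870_at	5.59E-01	1.64E-01	6.85E-02
DKKL1	pbmc	220284_at	7.46E-01	5.82E-01	-3.62E-02
DKKL1	pbtc	220284_at	8.55E-01	5.41E-01	-2.86E-02
DPH5	pbmc	219590_x_at	3.30E-02	4.62E-03	2.44E-01
DPH5	pbtc	222360_at	6.86E-01	2.73E-01	8.58E-02
EVI5	pbmc	208298_at	4.30E-01	2.20E-01	1.81E-02
EVI5	pbtc	209717_at	1.71E-01	1.55E-02	9.28E-02
EXTL2	pbmc	209537_at	5.74E-02	9.85E-03	-4.79E-01
EXTL2	pbtc	209537_at	9.79E-01	9.06E-01	-6.33E-03
FCRL3	pbmc	231093_at	2.36E-01	7.80E-02	4.12E-01
FCRL3	pbtc	231093_at	6.71E-01	2.57E-01	-2.54E-01
GALC	pbmc	211810_s_at	7.77E-04	3.31E-05	-1.21
GALC	pbtc	204417_at	9.20E-01	7.01E-01	-4.98E-02
GFI1	pbmc	206589_at	7.79E-01	6.28E-01	8.90E-02
GFI1	pbtc	206589_at	1.43E-01	1.12E-02	-3.77E-01
HLA-DOA	pbmc	226878_at	1.39E-02	1.47E-03	6.25E-01
HLA-DOA	pbtc	226878_at	2.70E-01	3.65E-02	-1.51E-01
HLA-DOB	pbmc	205671_s_at	1.06E-04	2.22E-06	1.57
HLA-DOB	pbtc	1554984_a_at	6.70E-01	2.55E-01	5.44E-02
IL2RA	pbmc	206341_at	3.36E-01	1.43E-01	1.84E-01
IL2RA	pbtc	211269_s_at	1.81E-01	1.74E-02	1.70E-01
IQCB1	pbmc	211707_s_at	7.91E-01	6.45E-01	3.46E-02
IQCB1	pbtc	211707_s_at	2.98E-01	4.41E-02	1.57E-01
MMEL1	pbmc	1552930_at	3.86E-01	1.81E-01	1.31E-01
MMEL1	pbtc	1552930_at	9.51E-01	8.03E-01	1.67E-02
MICB	pbmc	205905_s_at	4.01E-01	1.93E-01	-1.43E-01
MICB	pbtc	205905_s_at	1.00E-01	5.93E-03	-1.99E-01
NFKBIL1	pbmc	209973_at	5.72E-01	3.63E-01	-5.42E-02
NFKBIL1	pbtc	209973_at	8.94E-01	6.31E-01	-2.17E-02
PSMB8	pbmc	209040_s_at	2.72E-02	3.57E-03	-2.92E-01
PSMB8	pbtc	209040_s_at	7.65E-01	3.71E-01	-9.26E-02
PSMB9	pbmc	204279_at	1.00E-01	2.16E-02	-2.69E-01
PSMB9	pbtc	204279_at	8.78E-01	5.92E-01	-7.76E-02
PSORS1C1	pbmc	220362_at	6.55E-01	4.62E-01	1.99E-02
PSORS1C1	pbtc	220362_at	9.08E-01	6.65E-01	-1.88E-02
PSORS1C2	pbmc	220635_at	3.38E-01	1.45E-01	1.94E-02
PSORS1C2	pbtc	220635_at	8.16E-01	4.59E-01	4.60E-02
TAP1	pbmc	202307_s_at	8.33E-01	7.09E-01	-4.37E-02
TAP1	pbtc	202307_s_at	4.66E-01	1.09E-01	-3.09E-01
TAP2	pbmc	204770_at	1.93E-02	2.27E-03	4.60E-01
TAP2	pbtc	204770_at	7.63E-01	3.69E-01	-1.47E-01
TNFRSF1A	pbmc	207643_s_at	3.58E-05	4.73E-07	-6.25E-01
TNFRSF1A	pbtc	207643_s_at	2.55E-03	6.18E-06	-5.85E-01
TMEM39A	pbmc	218615_s_at	9.74E-03	9.34E-04	-4.58E-01
TMEM39A	pbtc	218615_s_at	1.17E-01	7.78E-03	-1.40E-01
TNFSF14	pbmc	207907_at	6.54E-03	5.54E-04	-8.60E-01
TNFSF14	pbtc	207907_at	1.68E-02	2.48E-04	-4.27E-01
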