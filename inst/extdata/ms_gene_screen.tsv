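gene_id	position	nsnp_setscreen	kb	p_setscreen	nsnp_sim	p_sim
AHI1	chr6:135648258.135814841	15	166.6	7.20E-09	15	1.00E-06
CD58	chr1:116883333.116902480	2	19.15	2.53E-08	2	1.00E-06
CDSN	chr6:31191792.31195913	3	4.121	0	3	1.00E-06
CLEC16A	chr16:10949695.11183414	55	233.7	1.62E-10	55	1.00E-06
COL11A2	chr6:33244123.33266876	9	22.75	1.31E-10	9	1.00E-06
DPH5	chr1:101245330.101258649	3	13.32	1.84E-09	3	1.00E-06
EVI5	chr1:92753827.92991364	15	237.5	1.18E-07	16	1.00E-06
EXTL2	chr1:101122894.101132803	3	9.909	2.48E-10	5	1.00E-06
FCRL3	chr1:155914722.155935902	4	21.18	8.13E-07	4	1.00E-06
HLA-DOA	chr6:33080865.33085293	9	4.428	7.66E-07	9	1.00E-06
HLA-DOB	chr6:32888702.32892598	6	3.896	0	6	1.00E-06
IL2RA	chr10:6102114.6141719	13	39.6	3.95E-07	14	1.00E-06
IQCB1	chr3:122983760.123026267	8	42.51	1.64E-07	8	1.00E-06
MICB	chr6:31580699.31584833	2	4.134	0	4	1.00E-06
MMEL1	chr1:2516606.2543484	4	26.88	4.59E-13	4	1.00E-06
TAP1	chr6:32921257.32927843	6	6.586	1.89E-09	6	1.00E-06
TMEM39A	chr3:120633526.120657228	5	23.7	1.44E-06	6	1.00E-06
TNFRSF1A	chr12:6310270.6319376	6	9.106	3.56E-07	6	1.00E-06
TNFSF14	chr19:6616020.6619972	2	3.952	1.27E-06	3	1.00E-06
DKKL1	chr19:54559725.54570008	3	10.28	2.16E-07	3	2.00E-06
GALC	chr14:87477641.87516629	10	38.99	1.65E-06	10	2.00E-06
GFI1	chr1:92713438.92717582	2	4.144	2.23E-06	2	2.00E-06
NFKBIL1	chr6:31623778.31633427	3	9.649	0	3	1.00E-06
PSMB8	chr6:32917826.32919607	3	1.781	0	3	1.00E-06
PSMB9	chr6:32930836.32933326	3	2.49	0	3	1.00E-06
PSORS1C1	chr6:31191792.31215712	14	23.92	0	14	1.00E-06
PSORS1C2	chr6:31213392.31215066	5	1.674	0	5	1.00E-06
TAP2	chr6:32903010.32912912	18	9.902	0	18	1.00E-06
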