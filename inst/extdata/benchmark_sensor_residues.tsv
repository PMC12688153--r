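protein	residue	predicted	sasa	am_avg
GPR4	E145	0	20.8	0.827
GPR4	D282	1	0.3	0.991
PSYR	D286	1	0	0.972
PSYR	D60	1	0	0.945
OGR1	E149	1	9.6	0.953
OGR1	D282	1	0.9	0.989
FCGRN	H189	1	0	0.875
ERD22	H12	1	9.7	0.993
CTNS	D205	1	0.1	0.984
CTNS	D305	0	23.4	0.995
TRPV1	E600	0	117.9	0.695
TRPV1	E649	0	115.2	0.805
MOT1	K38	1	8.1	0.993
MOT1	D309	1	0.9	0.996
SL9A1	D172	1	14.7	0.990
B3AT	R760	1	2.1	0.914
S4A4	E135	1	0	0.989
S4A4	R342	1	4.6	0.999
CAH2	H64	0	35.3	0.832
CAH2	H94	0	17.5	0.975
CAH2	H96	1	0.7	0.984
CAH2	H119	1	1.9	0.976
COF1/COF2/DEST	H133	0	27.4	0.925
TLN1	H2418	0	147.6	0.380
PCFT	E185	0	37.3	0.940
PCFT	H281	0	32.0	0.591
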