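protein	from_review	n_pass
ASIC1	1	NA
ASIC2	1	NA
GPR4	1	9
PSYR	1	9
OGR1	1	9
TRPV1	1	9
MOT1	1	5
SL9A1	1	6
B3AT	1	10
S4A4	1	10
CAH2	1	10
CAH9	1	NA
CAH12	1	NA
DEST	1	1
COF1	1	1
COF2	1	3
TLN1	1	9
MCF2L	1	NA
FCGRN	0	9
ERD22	0	4
CTNS	0	10
ASSY	0	NA
PCFT	0	3
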