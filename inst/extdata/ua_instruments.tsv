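SNP	CHR	POS	EA	OA	BETA	SE	P	N
rs10305838	4	148400256	C	T	0.130	0.016	1.28e-16	456468
rs11206803	1	56877509	T	C	0.070	0.013	2.61e-8	456468
rs11584234	1	115907009	G	T	-0.095	0.017	9.79e-9	456468
rs17637472	17	47461433	A	G	0.081	0.015	2.79e-8	456468
rs2240191	12	113335731	T	G	0.104	0.018	3.30e-9	456468
rs2288873	19	41852979	G	A	-0.070	0.013	3.35e-8	456468
rs28720373	4	148291242	T	C	-0.083	0.015	3.09e-8	456468
rs4409766	10	104616663	C	T	-0.108	0.017	3.30e-10	456468
rs7176070	15	79033489	C	T	-0.083	0.013	7.16e-10	456468
rs75346744	2	21520627	G	A	0.219	0.040	3.28e-8	456468
rs79780963	10	104952499	T	C	-0.105	0.018	5.53e-9	456468
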