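sample_id	site	total_mapped_reads	oste	ry	rx	prot
ST-30	ST	0	Indet	Indet	Indet	M
ST-38	ST	0	Indet	Indet	Indet	M
RTKT-5	RTKT	202	M*	Indet	Indet	M
RTKT-21	RTKT	384	Indet	Indet	F*	F
RTKT-4	RTKT	602	M*	Indet	Indet	M
RTKT-3	RTKT	614	M*	Indet	F*	M
RTKT-14	RTKT	884	Indet	Indet	F*	F
RTKT-22	RTKT	1499	M*	Indet	M*	M
RTKT-7C	RTKT	2036	Indet	F*	M*	F
RTKT-8	RTKT	2249	Indet	Indet	M*	M
ST-21	ST	3838	Indet	F*	F*	M
ST-55	ST	3940	Indet	F*	F*	F
ST-8	ST	5256	Indet	M*	M	M
ST-5A	ST	6605	Indet	F	F*	M
ST-49B	ST	8171	M	M*	M	M
ST-31	ST	8491	F*	F*	F*	F
ST-29	ST	12880	F*	M*	M*	F
RTKT-12	RTKT	16208	Indet	M*	M	M
ST-13	ST	17650	M	M*	M	M
ST-35	ST	19768	M	F*	F*	M
ST-58B	ST	23515	Indet	F*	F*	F
ST-23	ST	24618	Indet	F	F*	F
RTKT-19	RTKT	33738	Indet	M*	M	M
ST-36	ST	35058	F	M*	M*	F
ST-40	ST	41720	M	Indet	Indet	M
ST-46	ST	42606	M	Indet	M*	M
RTKT-23	RTKT	42930	F*	F	F*	M
ST-51	ST	45661	M	M	M	M
ST-27A	ST	47008	F	F	F*	F
ST-47	ST	56495	M	F*	F*	M
ST-10	ST	66934	M	M	M	M
ST-5B	ST	75045	Indet	Indet	M	M
ST-57A	ST	88870	F	F	F*	F
RTKT-20	RTKT	95017	Indet	F	F	F
ST-15	ST	131763	Indet	M*	M	M
ST-44	ST	136755	M	M	M	M
ST-26	ST	140759	Indet	M*	M	M
ST-58A	ST	174112	F*	F	F*	F
RTKT-7A	RTKT	186704	F*	F	F*	F
ST-7	ST	218316	Indet	M	M	M
RTKT-16	RTKT	298184	Indet	F	F*	F
ST-32	ST	311636	Indet	M	M	M
ST-12	ST	577053	M*	M	M	M
ST-42	ST	638050	Indet	M	M	M
ST-9	ST	737923	Indet	M	M	M
RTKT-10	RTKT	820699	F*	F	F	F
RTKT-17	RTKT	964774	Indet	M	M	M
ST-52	ST	1052930	M*	M	M	M
ST-56	ST	1404346	M*	M	M	M
ST-6	ST	1581177	F	F	F	F
ST-62	ST	6376553	Indet	F	F	F
ST-63	ST	10796470	Indet	M	M	M
ST-53	ST	22121564	F	F	F	F
ST-54	ST	24679707	Indet	F	F	F
ST-48	ST	39132506	F	F	F*	F
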