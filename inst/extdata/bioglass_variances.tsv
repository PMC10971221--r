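comparison	experiment	accession	p_value	var_ref	var_trt	abs_var_diff
ctrl_vs_doped	SBA2	P02458	0.77209	1.27	2.26	0.99
ctrl_vs_doped	SBA2	P19338	0.7934	2.76	0.16	2.6
ctrl_vs_doped	SBA2	P14923	0.90066	3.85	1.55	2.3
ctrl_vs_doped	SBA2	Q9Y4Z0	0.37355	13.0	0.72	12.28
ctrl_vs_doped	SBA3	P02656	0.19829	0.73	0.18	0.55
ctrl_vs_doped	SBA3	P38571	0.85016	0.21	2.61	2.4
ctrl_vs_doped	SBA3	Q9P2E9	0.03166	0.22	0.08	0.14
ctrl_vs_doped	SBA3	P02765	0.51954	1.8	0.2	1.6
ctrl_vs_doped	SBA3	P49720	0.80732	1.44	1.55	0.11
ctrl_vs_doped	SBA3	P46940	0.67908	0.51	1.66	1.15
ctrl_vs_doped	SBA3	P59665	0.40182	8.47	2.79	5.68
ctrl_vs_doped	ST	P24821-4	0.4643	1.02	1.73	0.71
ctrl_vs_doped	ST	P26583	0.20189	0.1	0.71	0.61
ctrl_vs_doped	ST	P22234	0.08797	0.5	0.17	0.33
ctrl_vs_doped	ST	P35555	0.04938	0.22	0.34	0.12
ctrl_vs_doped	ST	P24821	0.05846	0.13	0.96	0.83
ctrl_vs_doped	ST	Q9P2E9	0.03078	0.32	0.23	0.09
ctrl_vs_doped	ST	P13611	0.16264	1.83	5.37	3.54
plast_vs_doped	SBA2	P35908	0.00245	0.07	0.28	0.21
plast_vs_doped	SBA2	P35527	0.00029	0.02	0.14	0.12
plast_vs_doped	SBA2	P04264	0.00015	0.01	0.25	0.24
plast_vs_doped	SBA2	P13645	0.00041	0.02	0.35	0.33
plast_vs_doped	SBA2	P60985	0.08047	0.27	0.84	0.57
plast_vs_doped	SBA2	P12111	0.00145	0.54	0.04	0.5
plast_vs_doped	SBA2	P08493	0.10463	2.05	1.65	0.4
plast_vs_doped	SBA3	P00734	0.0291	0.25	0.01	0.24
plast_vs_doped	SBA3	P12111	0.05029	0.54	0.63	0.09
plast_vs_doped	SBA3	P35908	0.00252	0.07	0.57	0.5
plast_vs_doped	SBA3	P35527	0.00038	0.02	0.53	0.51
plast_vs_doped	SBA3	P13645	0.00059	0.02	0.79	0.77
plast_vs_doped	SBA3	P04264	0.00018	0.01	0.66	0.65
plast_vs_doped	ST	O94985	0.02078	0.01	0.26	0.25
plast_vs_doped	ST	P22234	0.03636	1.17	0.17	1.0
plast_vs_doped	ST	P02545	0.08999	2.02	0.17	1.85
plast_vs_doped	ST	P04264	0.00015	0.01	0.07	0.06
plast_vs_doped	ST	P35527	0.00079	0.02	0.29	0.27
plast_vs_doped	ST	Q16363	0.25842	2.89	1.69	1.2
plast_vs_doped	ST	P13645	0.00037	0.02	0.07	0.05
plast_vs_doped	ST	P35908	0.00244	0.07	0.16	0.09
plast_vs_doped	ST	P00734	0.02785	0.25	0.03	0.22
plast_vs_doped	ST	P26022	0.08427	0.41	2.51	2.1
plast_vs_doped	ST	P60985	0.04855	0.27	0.69	0.42
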