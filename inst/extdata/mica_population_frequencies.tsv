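allele	novel	DE_Germany	PL_Poland	UK_British/Irish	ZA_White	ZA_Black	CL_Non-Indigenous	DE_Turkey
MICA*008	N	0.43643	0.39556	0.50505	0.43489	0.27694	0.19437	0.21419
MICA*002#	N	0.11496	0.13317	0.08822	0.12418	0.22484	0.31115	0.14243
MICA*009#	N	0.08733	0.09382	0.06250	0.07692	0.04536	0.08630	0.19687
MICA*010#	N	0.07777	0.05242	0.06370	0.07567	0.00049	0.06604	0.02337
MICA*004	N	0.06501	0.07199	0.07644	0.07466	0.24470	0.10432	0.08111
MICA*007	N	0.04845	0.06378	0.04736	0.03796	0.00221	0.01570	0.02475
MICA*018	N	0.03602	0.05950	0.02188	0.03042	0.02869	0.02330	0.07204
MICA*017	N	0.03321	0.03390	0.03413	0.03142	0.00025	0.01854	0.01320
MICA*012	N	0.02145	0.02338	0.02380	0.01961	0.01839	0.01276	0.04482
MICA*016	N	0.01886	0.02238	0.00697	0.02187	0.00196	0.02188	0.09926
MICA*011	N	0.01846	0.01115	0.02788	0.03117	0.01618	0.04487	0.02255
MICA*027#	N	0.01577	0.01856	0.00913	0.01232	0.00037	0.04659	0.02035
MICA*019	N	0.00838	0.00578	0.01875	0.00804	0.05431	0.01509	0.00605
MICA*001	N	0.00778	0.00352	0.00889	0.00930	0.01349	0.02036	0.00055
MICA*006	N	0.00425	0.00436	0.00120	0.00302	0.00000	0.00162	0.02942
MICA*015	N	0.00079	0.00063	0.00072	0.00251	0.04634	0.00436	0.00137
MICA*029	N	0.00069	0.00042	0.00000	0.00025	0.00025	0.00051	0.00110
MICA*068	N	0.00054	0.00063	0.00048	0.00000	0.00907	0.00334	0.00027
MICA*047#	N	0.00031	0.00063	0.00024	0.00025	0.00000	0.00091	0.00082
MICA*072	N	0.00031	0.00025	0.00024	0.00000	0.00000	0.00000	0.00000
MICA*045	N	0.00028	0.00008	0.00024	0.00126	0.00049	0.00051	0.00110
NEW	N	0.00026	0.00008	0.00024	0.00000	0.00147	0.00030	0.00137
MICA*070	N	0.00026	0.00008	0.00024	0.00000	0.00000	0.00000	0.00000
MICA*030	N	0.00018	0.00013	0.00000	0.00075	0.00760	0.00041	0.00027
MICA*052	N	0.00018	0.00038	0.00024	0.00000	0.00000	0.00314	0.00000
MICA*107N	Y	0.00016	0.00126	0.00000	0.00000	0.00000	0.00000	0.00000
MICA*141	Y	0.00014	0.00038	0.00000	0.00000	0.00000	0.00000	0.00027
MICA*089	Y	0.00012	0.00000	0.00000	0.00000	0.00000	0.00000	0.00000
MICA*119	Y	0.00010	0.00004	0.00000	0.00000	0.00000	0.00132	0.00000
MICA*136	Y	0.00009	0.00008	0.00000	0.00025	0.00000	0.00000	0.00055
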