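hostGene	bsj	log2FC	padj	meanG1	meanG2
SVIL	10:29512734-29531288	7.3	0.0000	0.5	47.5
AMY2B	1:103565434-103575540	4.5	0.0000	2.3	27.1
HIPK3	11:33286412-33287511	2.5	0.0979	37.0	213.8
SLC43A1	11:57491223-57491862	3.2	0.0000	6.4	43.0
TRAF5	1:211353238-211354467	3.1	0.0000	5.1	44.3
ITGA7	12:55700898-55701154	5.3	0.0007	22.5	903.0
SNHG12	1:28580559-28581229	6.2	0.0000	1.0	25.9
RPPH1	14:20343123-20343272	3.2	0.0000	41.4	359.3
RPPH1	14:20343123-20343277	5.1	0.0008	4.3	122.8
RPPH1	14:20343128-20343277	3.3	0.0000	39.0	373.9
MYOCD	17:12705127-12723008	6.8	0.0000	0.5	32.8
CircClust	17:79644136-79646334	5.4	0.0003	2.2	83.4
ZNF208	19:21974728-21988909	3.0	0.0000	52.7	419.3
PPP1R13L	19:45398004-45398339	4.2	0.0215	3.8	55.9
FER1L4	20:35595476-35595754	3.2	0.0097	4.5	36.0
AF165147.1	21:28377945-28417158	6.4	0.0000	1.8	145.7
SMTN	22:31097268-31104387	6.3	0.0001	1.2	71.9
SLC8A1	2:40428472-40430304	3.3	0.0007	7.0	59.2
GRHL1	2:9995878-9999029	4.5	0.0000	2.4	30.3
ABTB1	3:127674390-127674600	3.8	0.0000	3.7	39.3
FNDC3B	3:172112451-172133546	3.5	0.0000	8.3	86.1
KCNN2	5:114404437-114404856	4.7	0.0008	2.2	56.6
CD2AP	6:47503279-47554766	4.5	0.0153	3.1	62.3
RAB23	6:57193841-57210445	5.4	0.0001	1.5	53.8
PGM5	9:68378198-68392473	4.5	0.0009	1.5	30.5
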