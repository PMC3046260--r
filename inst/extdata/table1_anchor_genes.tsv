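probeset_id	gene_symbol	compartment	raw	median_other	fold_change_printed
1427034_at	Ace	EPT	916.2	74.5	12.3
1424758_s_at	Acsm1	EPT	1862.1	48.6	38.3
1451760_s_at	AI317395	EPT	501.6	39.9	13
1429254_at	Aqp11	EPT	708.2	49.9	14
1451681_at	BC089597	EPT	692.0	31.1	22.2
1453011_at	Bdh2	EPT	794.5	75.0	11
1416051_at	C2	EPT	897.8	57.1	15.7
1418013_at	Cml1	EPT	7504.8	168.1	45
1447112_s_at	Cryl1	EPT	2542.7	243.0	10
1417382_at	Entpd5	EPT	4464.5	344.0	13
1448470_at	Fbp1	EPT	3072.5	28.0	110
1435459_at	Fmo2	EPT	313.3	20.3	15
1424995_at	Glyctk	EPT	278.4	22.3	12.5
1416980_at	Mettl7b	EPT	925.0	44.8	21
1455099_at	Mogat2	EPT	1374.9	100.6	13.7
1432099_a_at	Prodh2	EPT	599.4	52.9	11
1426595_at	Slc18a1	EPT	3224.5	131.7	24
1417072_at	Slc22a6	EPT	2460.4	66.4	37.1
1416316_at	Slc27a2	EPT	10454.9	88.3	118
1448741_at	Slc3a1	EPT	4187.5	43.9	95.4
1422899_at	Slc6a20b	EPT	1178.6	32.9	35.8
1438183_x_at	Sord	EPT	834.2	45.2	18.5
1418916_at	Spp2	EPT	10339.9	53.6	192.9
1447800_x_at	Tcn2	EPT	12193.4	1129.0	11
1449890_at	Ugt2b37	EPT	1991.4	11.2	179
1426252_a_at	Umod	LoH	323.9	11.9	27.3
1449104_at	Upk3a	MCD	1387.7	43.9	31.6
1422567_at	Fam129a	MCD	720.7	51.9	14
1430641_at	Gsdmc4	MCD	2080.5	69.6	29.9
1439117_at	Clmn	MCD	230.7	53.5	4.3
1436099_at	AI836003	MCD	328.9	101.2	3.2
1456391_at	Tdrd5	RC	356.6	45.5	7.8
1418396_at	Gpsm3	RC	328.7	105.4	3.1
1446524_at	C230096N06	RC	309.7	23.2	13.3
1428664_at	Vip	RC	193.0	21.6	8.9
1419127_at	Npy	RV	740.6	108.5	6.8
1460616_at	Slco4c1	UT	1042.8	15.8	66.0
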