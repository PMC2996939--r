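protein_id	n_sites	n_ps	n_pt	n_py	length	go6139	hotspot
AT5G52040.1	22	19	1	2	357	TRUE	TRUE
AT2G29210.1	16	13	1	2	879	TRUE	FALSE
AT2G37340.1	13	13	0	0	291	TRUE	FALSE
AT5G64200.1	13	13	0	0	304	TRUE	TRUE
AT2G43680.1	13	11	2	0	669	FALSE	FALSE
AT3G55460.1	13	11	0	2	263	TRUE	TRUE
AT1G35580.1	12	10	2	0	552	FALSE	TRUE
AT3G25500.1	12	12	0	0	1052	FALSE	FALSE
AT3G63400.1	12	11	1	0	571	TRUE	FALSE
AT5G47690.1	12	10	2	0	1606	FALSE	FALSE
AT3G23900.1	11	11	0	0	988	FALSE	FALSE
AT2G18960.1	11	5	4	2	950	FALSE	FALSE
AT2G20960.1	11	4	7	0	749	FALSE	FALSE
AT3G53500.1	10	9	0	1	244	TRUE	TRUE
AT4G33240.1	10	8	2	0	1758	FALSE	TRUE
AT5G01400.1	10	7	3	0	1468	TRUE	TRUE
AT1G31870.1	10	10	0	0	562	FALSE	FALSE
AT5G47430.1	10	9	0	1	893	FALSE	FALSE
AT4G32420.1	9	8	0	1	838	FALSE	FALSE
AT5G10470.1	9	9	0	0	1274	FALSE	FALSE
AT4G02510.1	9	8	1	0	1504	FALSE	FALSE
AT4G31160.1	9	7	2	0	1847	FALSE	TRUE
AT3G26935.1	9	6	2	1	444	FALSE	FALSE
AT5G47910.1	9	9	0	0	922	FALSE	FALSE
AT5G61150.1	9	9	0	0	626	FALSE	FALSE
AT5G43310.1	9	5	4	0	1238	FALSE	FALSE
AT5G40450.1	9	8	1	0	2890	FALSE	FALSE
AT3G13570.1	9	8	1	0	263	TRUE	TRUE
AT3G61860.1	9	8	0	1	265	TRUE	FALSE
AT1G48920.1	9	8	1	0	558	FALSE	FALSE
AT1G19870.1	9	9	0	0	795	FALSE	FALSE
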