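arm_id	chrom	arm	het_start_mb	het_end_mb	proximal_clone	d_het_prox_mb	distal_clone	core_span_mb	status
1p	chr1	p	121.5	NA	RP11-803J8	0.015	CTD-3138A9	0.98	incomplete_no_junction
1q	chr1	q	NA	142.6	RP11-15M9	0.76	CTD-2326L14	1.46	incomplete_segdup
2p	chr2	p	90.5	NA	CTD-2269O20	0	RP11-1023H22	0.61	complete
2q	chr2	q	NA	96.8	RP11-139J5	0	RP11-245P4	0.96	complete
3p	chr3	p	87.9	NA	RP11-424C9	0	RP11-598A10	0.71	complete
3q	chr3	q	NA	93.9	RP11-259L20	0	RP11-625F19	0.87	complete
4p	chr4	p	48.2	NA	RP11-260K18	0	CTD-2057N12	0.88	complete
4q	chr4	q	NA	52.7	RP11-98B6	0	RP11-600M5	0.76	complete
5p	chr5	p	46.1	NA	RP11-10F16	0	RP11-134N5	0.91	complete
5q	chr5	q	NA	50.7	RP11-463E10	0	CTD-3113M11	0.33	complete
6p	chr6	p	58.7	NA	RP11-136G2	0	RP11-799H20	1.02	complete
6q	chr6	q	NA	63.3	RP11-448N11	0	RP11-78B14	0.30	complete
7p	chr7	p	58.0	NA	CTD-2593N8	0	RP11-114G11	0.66	complete
7q	chr7	q	NA	61.7	CTD-2245O1	0	RP11-45N18	0.84	complete
8p	chr8	p	43.1	NA	RP11-73M19	0	RP11-577C12	0.79	complete
8q	chr8	q	NA	48.1	CTD-2563N10	0	RP11-367A12	0.56	complete
9p	chr9	p	47.3	NA	RP11-606B18	0.37	RP11-361G22	0.64	incomplete_segdup
9q	chr9	q	NA	65.9	CTD-2508M5	0	CTD-2050L17	0.49	complete
10p	chr10	p	38.0	NA	CTD-3195G22	0	RP11-739D18	0.58	complete
10q	chr10	q	NA	42.3	RP11-80L2	0.08	RP11-351D16	1.32	incomplete_no_junction
11p	chr11	p	51.6	NA	RP11-100E23	0.06	RP11-318O24	1.00	incomplete_no_junction
11q	chr11	q	NA	55.7	CTD-3202L3	0	RP11-720L5	0.85	complete
12p	chr12	p	33.3	NA	RP11-460N10	0	RP11-8P13	0.48	complete
12q	chr12	q	NA	38.2	RP11-496H24	0	RP11-715M8	0.68	complete
13q	chr13	q	NA	19.5	RP11-294G16	0	RP11-71I1	0.32	complete
14q	chr14	q	NA	19.1	RP11-639F13	0	RP11-77E23	0.90	complete
15q	chr15	q	NA	20.7	RP11-108C1	0	RP11-666L22	0.34	complete
16p	chr16	p	34.6	NA	RP11-488I20	0	RP11-1088B6	0.32	complete
16q	chr16	q	NA	47.0	RP11-627O2	0	RP11-671L23	0.36	complete
17p	chr17	p	22.2	NA	RP11-718K3	0	RP11-937K3	0.51	complete
17q	chr17	q	NA	25.8	RP11-1049N9	0	RP11-59G20	0.52	complete
18p	chr18	p	15.4	NA	RP11-1133K23	0	RP11-1025M21	0.52	complete
18q	chr18	q	NA	19.0	RP11-746M23	0	RP11-60G3	0.66	complete
19p	chr19	p	24.4	NA	RP11-350E11	0	RP11-642I13	0.86	complete
19q	chr19	q	NA	28.6	CTD-2045N7	0	RP11-347I6	0.95	complete
20p	chr20	p	25.6	NA	RP11-161K13	0	RP11-156D15	0.49	complete
20q	chr20	q	NA	29.4	CTD-2311M18	0.02	RP11-1147I19	1.17	incomplete_no_junction
21q	chr21	q	NA	14.3	RP11-203F20	0.13	RP11-1025M7	0.93	incomplete_no_junction
22q	chr22	q	NA	17.9	RP11-958H20	0	RP11-81B3	0.71	complete
Xp	chrX	p	58.1	NA	CTD-2225J11	0	RP11-936C8	0.96	complete
Xq	chrX	q	NA	63.0	RP11-943J20	0	RP11-284B18	0.54	complete
Yp	chrY	p	11.6	NA	RP11-108I14	1.50	NA	NA	unavailable_no_map
Yq	chrY	q	NA	13.4	RP11-1100G7	0	RP11-91N9	1.1	complete
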