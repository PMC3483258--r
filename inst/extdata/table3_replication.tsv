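# Published replication of three DMRs in an independent sample group
# (2 humans H4-H5 vs 4 rhesus macaques M4-M7), with the printed difference,
# raw p, corrected p (raw x 3), and the p value pooling all samples.
region_id	unit_id	gene	human:H4	human:H5	macaque:M4	macaque:M5	macaque:M6	macaque:M7	printed_difference	printed_p	printed_p_corrected	printed_p_all
DMR103	region_mean	K6IRS2	0.289	0.252	0.936	0.852	0.902	0.958	-0.641	6.22E-05	1.9E-04	1.7E-08
DMR143	region_mean	RNF32	0.403	0.427	0.930	0.875	0.925	NA	-0.495	2.6E-04	7.8E-04	2.3E-08
DMR8	region_mean	ICAM1	0.103	0.200	0.455	0.520	0.410	0.500	-0.320	2.5E-03	7.5E-03	9.7E-08
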