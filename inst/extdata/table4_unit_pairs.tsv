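# Published per-sample methylation of the 25 orthologously paired CpG unit
# groups called significantly different between humans (H1-H3) and rhesus
# macaques (M1-M3). human_units / rhesus_units give the member CpG unit
# labels on each side of the pairing (NA = position with no CpG unit on
# that side); printed corrected p was adjusted across all 688 paired units
# of the full screen and is therefore not recomputable from this table.
region_id	unit_id	human_units	rhesus_units	human:H1	human:H2	human:H3	macaque:M1	macaque:M2	macaque:M3	printed_difference	printed_p	printed_p_corrected
DMR8	u01	16 NA	13 14	0.26	0.24	0.25	0.73	0.72	0.73	-0.48	2.3E-07	7.9E-05
DMR8	u02	15	12	0.17	0.12	0.19	0.55	0.58	0.49	-0.38	3.5E-04	8.6E-03
DMR13	u03	NA 4 5	13 12 NA	0.41	NA	0.41	0.17	0.12	0.14	0.27	7.5E-04	1.3E-02
DMR13	u04	14 15 16	NA 1 NA	0.49	NA	0.57	0.29	0.3	0.28	0.24	4.4E-03	4.0E-02
DMR13	u05	1 2	15 14	0.37	0.44	0.48	0.17	0.17	0.02	0.32	6.1E-03	5.0E-02
DMR22	u06	7 8 9 10	7 8 9 10	0.23	0.23	0.12	0.43	0.48	0.41	-0.25	4.3E-03	4.0E-02
DMR51	u07	17 18 19	16 17 18	0.07	0.02	0.05	NA	0.27	0.3	-0.24	1.6E-03	2.2E-02
DMR57	u08	9 NA 10 11	8 9 10 NA	0.11	0.13	0.08	0.67	NA	0.66	-0.56	8.8E-05	5.0E-03
DMR57	u09	29 NA	25 26	0	0	0	0.18	NA	0.25	-0.22	3.7E-03	3.8E-02
DMR75	u10	NA 1	1 2	0.76	0.75	0.8	1.00	1.00	1.00	-0.23	1.1E-04	5.1E-03
DMR76	u11	26 27	NA 1	1.00	1.00	1.00	0.62	0.59	0.69	0.37	2.4E-04	7.3E-03
DMR103	u12	9	9	0.01	0.03	0.03	0.77	0.69	0.6	-0.66	1.8E-04	6.5E-03
DMR103	u13	19	19	0.38	0.33	0.38	0.97	0.91	0.81	-0.53	4.2E-04	9.7E-03
DMR103	u14	4	3	0.14	0.07	0.13	1.00	0.81	0.75	-0.74	7.0E-04	1.3E-02
DMR103	u15	10 11 12 NA	10 11 NA 12	0.21	0.22	0.21	0.99	0.74	0.76	-0.62	1.5E-03	2.1E-02
DMR103	u16	5 NA 6 NA	4 5 NA 6	0.05	0.04	0.06	0.96	NA	0.74	-0.81	2.3E-03	2.6E-02
DMR103	u17	24	25	0.24	0.26	0.31	0.73	0.98	0.71	-0.54	3.9E-03	3.9E-02
DMR122	u18	3 4 5	NA 5 NA	0.87	0.77	0.87	0.26	0.26	0.24	0.58	6.8E-05	5.0E-03
DMR127	u19	18 19 NA	18 19 20	0.11	0.04	0.10	0.28	0.3	0.30	-0.21	7.8E-04	1.3E-02
DMR131	u20	43 44	31 32	0.21	0.24	0.27	0	0.03	0.01	0.23	3.1E-04	7.9E-03
DMR139	u21	15 16 NA 17 18 19	8 9 10 NA 11 NA	0.13	0.21	0.17	0.36	0.39	0.41	-0.22	1.4E-03	2.0E-02
DMR141	u22	45 46 47	43 NA 44	0.25	0.20	0.20	0.02	0.01	0.01	0.21	2.9E-04	7.9E-03
DMR143	u23	NA 3 NA	4 NA 5	0.30	0.29	0.35	1.00	1.00	0.99	-0.68	3.5E-06	7.9E-04
DMR143	u24	7	9	0.27	0.22	0.25	0.96	0.86	0.84	-0.64	8.8E-05	5.0E-03
DMR143	u25	5	7	0.29	0.27	0.33	0.85	0.75	0.80	-0.50	1.2E-04	5.1E-03
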