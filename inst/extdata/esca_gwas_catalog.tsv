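pmid	gene	variant	cancer_type	year	model	ethnicity	or_point	ci_low	ci_high	egger_p	bias_tested	het_p	i_squared	n_studies	n_total	n_cases	n_controls	test_count	calc_low	calc_high	maf	maf_case	p_reported	gwas_replicated	bias_override	source	significant	headline	power_pub	fprp_pub
20729852	PLCE1	rs3765524	EC	2010	additive	Asian	1.35	1.22	1.49	Na	FALSE	Na	Na	Na	5417	2115	3302	Na	Na	Na	0.207	0.258	1.74E-09	TRUE	Na	gwas	TRUE	TRUE	0.982	0.000
20729852	PLCE1	rs2274223	EC	2010	additive	Asian	1.43	1.37	1.49	Na	FALSE	Na	Na	Na	5417	2115	3302	Na	Na	Na	Na	Na	7.46E-56	TRUE	Na	gwas	TRUE	TRUE	0.842	0.000
20729853	C20orf54	rs13042395	EC	2010	additive	Asian	0.86	0.82	0.90	Na	FALSE	Na	Na	Na	22336	9053	13283	Na	Na	Na	Na	Na	1.21E-11	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
20729853	HEATR	rs4785204	EC	2012	additive	Asian	1.24	1.18	1.29	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.26	Na	2.24E-20	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	HEATR	rs7206735	EC	2012	additive	Asian	1.20	1.15	1.26	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.28	Na	1.97E-16	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	HAP1	rs6503659	EC	2012	additive	Asian	1.27	1.20	1.34	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.13	Na	2.73E-10	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	XBP1	rs2239815	EC	2012	additive	Asian	1.18	1.13	1.23	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.37	Na	3.88E-15	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	ST6GAL1	rs2239612	EC	2012	additive	Asian	1.21	1.15	1.27	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.19	Na	5.74E-15	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	SMG6	rs17761864	EC	2012	additive	Asian	1.21	1.14	1.28	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.14	Na	2.21E-11	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	PTPN2	rs2847281	EC	2012	additive	Asian	1.20	1.14	1.26	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.16	Na	2.49E-11	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	CHEK2	rs4800983	EC	2012	additive	Asian	1.27	1.21	1.34	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.20	Na	1.94E-22	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
22960999	CHEK2	rs1033667	EC	2012	additive	Asian	1.25	1.19	1.30	Na	FALSE	Na	Na	Na	20787	10123	10664	Na	Na	Na	0.25	Na	4.85E-22	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
24121790	KLF5	rs1924966	EC	2015	additive	Asian	0.84	0.80	0.89	Na	FALSE	Na	Na	Na	12356	6177	6179	Na	Na	Na	0.40	0.35	1.37E-10	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
26315552	KLF5	rs115797771	EC	2015	additive	Asian	0.69	0.62	0.78	Na	FALSE	Na	Na	Na	12356	6177	6179	Na	Na	Na	0.06	0.05	2.32E-10	TRUE	Na	gwas	TRUE	TRUE	0.709	0.000
26315552	KLF5	rs58090485	EC	2015	additive	Asian	0.69	0.62	0.77	Na	FALSE	Na	Na	Na	12356	6177	6179	Na	Na	Na	0.07	0.05	1.23E-10	TRUE	Na	gwas	TRUE	TRUE	0.731	0.000
26315552	TMEM173	rs7447927	EC	2014	additive	Asian	0.85	0.82	0.88	Na	FALSE	Na	Na	Na	30286	15667	14619	Na	Na	Na	Na	Na	7.72E-20	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
25129146	ATP1B2	rs1642764	EC	2014	additive	Asian	0.88	0.85	0.91	Na	FALSE	Na	Na	Na	30281	15474	14807	Na	Na	Na	Na	Na	3.10E-13	TRUE	Na	gwas	TRUE	TRUE	1.000	0.000
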