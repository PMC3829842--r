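method_id	sampling_type	category	med_p	med_rank	fp_pct_1	z_sens	z_prior	z_spec	z_sum	rank_in_category
PLAGE	subject	I	0.0022	25.0	1.1	-1.5	-0.4	NA	-1.86	1
GLOBALTEST	subject	I	0.0001	27.9	2.0	-1.5	-0.2	NA	-1.69	2
PADOG	subject	I	0.0960	9.7	2.5	0.0	-1.5	NA	-1.45	3
ORA	gene	I	0.0732	18.3	2.5	-0.4	-0.9	NA	-1.21	4
SAFE	subject	I	0.1065	18.8	1.3	0.2	-0.8	NA	-0.64	5
SIGPATHWAY_Q2	subject	I	0.0565	38.0	0.9	-0.6	0.5	NA	-0.09	6
GSA	subject	I	0.1420	21.0	1.3	0.7	-0.7	NA	0.07	7
SSGSEA	subject	I	0.0808	40.3	1.0	-0.2	0.7	NA	0.45	8
ZSCORE	subject	I	0.0950	39.8	1.0	0.0	0.7	NA	0.65	9
GSEA	subject	I	0.1801	33.1	2.3	1.3	0.2	NA	1.52	10
GSVA	subject	I	0.1986	51.5	1.1	1.6	1.5	NA	3.10	11
CAMERA	subject	I	0.3126	43.0	0.5	3.4	0.9	NA	4.30	12
MRGSE	gene	II	0.0100	18.8	4.9	-0.59	-1.68	-1.27	-3.54	1
GSEAP	gene	II	0.0644	36.2	15.8	0.59	0.02	-0.08	0.53	2
GAGE	gene	II	0.0024	35.9	37.9	-0.76	-0.02	2.33	1.56	3
SIGPATHWAY_Q1	gene	II	0.1165	49.7	17.2	1.72	1.33	0.08	3.14	4
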