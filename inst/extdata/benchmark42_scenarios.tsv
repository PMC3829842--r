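method_id	category	overall	small_n	large_n	small_set	large_set	paired	unpaired	small_effect	large_effect
PLAGE	I	1	1	4	2	3	12	2	3	3
GLOBALTEST	I	2	2	1	3	5	6	1	2	4
PADOG	I	3	3	2	1	2	1	3	1	1
ORA	I	4	4	3	5	1	2	4	5	2
SAFE	I	5	7	5	4	8	8	5	4	6
SIGPATHWAY_Q2	I	6	5	8	8	4	5	7	8	8
GSA	I	7	9	6	7	6	11	6	6	11
SSGSEA	I	8	8	7	6	12	4	8	9	5
ZSCORE	I	9	6	10	10	7	9	10	7	9
GSEA	I	10	10	9	9	11	10	9	10	7
GSVA	I	11	11	11	11	9	3	11	11	10
CAMERA	I	12	12	12	12	10	7	12	12	12
MRGSE	II	1	1	1	1	2	1	1	1	1
GSEAP	II	2	2	2	2	1	2	2	2	2
GAGE	II	3	3	3	3	4	3	3	3	3
SIGPATHWAY_Q1	II	4	4	4	4	3	4	4	4	4
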