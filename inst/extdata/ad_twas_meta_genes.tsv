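chrom	start	end	gene	z_meta	p_meta	z_AA	z_NHW	z_HISP
2	126656133	126696667	GYPC	-4.555	5.242e-06	-1.213	-4.433	-0.292
2	127048027	127107288	BIN1	5.176	2.269e-07	2.056	4.734	1.856
8	27311482	27459391	PTK2B	4.482	7.380e-06	0.453	4.560	-0.406
11	47331406	47352702	MYBPC3	6.162	7.169e-10	-1.183	6.283	1.148
11	60200270	60243137	MS4A4E	7.311	2.651e-13	-1.438	7.730	-0.610
11	85657742	85682908	CREBZF	-5.788	7.140e-09	1.103	-5.861	-1.356
19	44890569	44903689	TOMM40	47.363	1.000e-50	10.800	47.700	-6.752
19	45178784	45216933	BLOC1S3	21.455	1.000e-50	2.760	21.200	2.017
19	45769709	45782552	DMPK	5.565	2.621e-08	0.099	5.500	1.130
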