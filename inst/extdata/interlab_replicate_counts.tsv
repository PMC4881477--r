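lab	sample	coverage	vendor_rep1	vendor_rep2	vendor_overlap	vendor_concordance	unified_rep1	unified_rep2	unified_overlap	unified_concordance
LabA	S1	181	200	200	178	89	60	62	54	88.52
LabB	S1	135	519	553	391	72.95	61	61	57	93.44
LabC	S1	NA	NA	NA	NA	NA	NA	NA	NA	NA
LabD	S1	103	2113	2144	367	17.24	42	41	33	79.52
LabE	S1	66	510	622	327	57.77	29	38	25	74.63
LabA	S2	144	1953	1949	1634	83.75	612	627	555	89.59
LabB	S2	119	3998	3991	3470	86.87	677	656	623	93.47
LabC	S2	170	1491	NA	NA	NA	642	NA	NA	NA
LabD	S2	78	10428	17944	1968	13.87	519	573	466	85.35
LabE	S2	82	4619	5201	3788	77.15	472	568	442	85
LabA	S3	242	336	338	296	87.83	104	110	97	90.65
LabB	S3	133	871	823	611	72.14	98	103	90	89.55
LabC	S3	242	187	NA	NA	NA	94	NA	NA	NA
LabD	S3	67	13892	23410	573	3.07	84	90	77	88.51
LabE	S3	80	1214	1255	699	56.62	72	84	64	82.05
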