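lab	replicate	total_detected	detected_in_truth	printed_sensitivity_pct
LabA	1	200	142	80
LabA	2	200	141	79
LabB	1	519	161	90
LabB	2	553	159	89
LabD	1	2113	104	58
LabD	2	2144	98	55
LabE	1	510	116	65
LabE	2	622	142	80
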