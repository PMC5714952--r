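species	region	length	at_percent	at_skew	gc_skew
S_maai	whole	15188	77.2	0.083	-0.158
S_maai	PCGs	10929	76.3	0.090	-0.161
S_maai	rrnL	1199	81.2	-0.121	0.181
S_maai	rrnS	739	78.6	-0.102	0.178
S_maai	tRNAs	1435	76.8	0.049	-0.112
S_maai	CR	847	81.9	-0.026	-0.100
S_nigrivalveus	whole	15235	76.5	0.093	-0.154
S_nigrivalveus	PCGs	10934	75.7	0.099	-0.160
S_nigrivalveus	rrnL	1204	79.8	-0.120	0.228
S_nigrivalveus	rrnS	743	77.7	-0.130	0.193
S_nigrivalveus	tRNAs	1440	76.1	0.067	-0.071
S_nigrivalveus	CR	902	83.1	-0.023	0.018
S_varius	whole	15207	75.9	0.075	-0.178
S_varius	PCGs	10938	74.7	0.079	-0.178
S_varius	rrnL	1203	79.7	-0.127	0.300
S_varius	rrnS	743	77.4	-0.106	0.274
S_varius	tRNAs	1439	76.1	0.043	-0.054
S_varius	CR	762	83.4	-0.014	-0.006
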