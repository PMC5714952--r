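gene	species	start_codon	stop_codon	length
nad2	S_maai	ATA	TAA	975
cox1	S_maai	ATG	TAA	1536
cox2	S_maai	ATA	T-	682
atp8	S_maai	ATT	TAA	153
atp6	S_maai	ATG	TAG	654
cox3	S_maai	ATG	TAA	780
nad3	S_maai	ATT	TAA	354
nad5	S_maai	TTG	T-	1666
nad4	S_maai	ATG	T-	1309
nad4l	S_maai	ATT	TAA	273
nad6	S_maai	ATA	TAA	477
cob	S_maai	ATG	TAA	1137
nad1	S_maai	ATA	TAA	933
nad2	S_nigrivalveus	ATA	TAA	975
cox1	S_nigrivalveus	ATG	TAG	1536
cox2	S_nigrivalveus	ATA	T-	682
atp8	S_nigrivalveus	ATT	TAA	153
atp6	S_nigrivalveus	ATG	TAA	654
cox3	S_nigrivalveus	ATG	TAA	780
nad3	S_nigrivalveus	ATC	TAA	354
nad5	S_nigrivalveus	TTG	TAA	1668
nad4	S_nigrivalveus	ATG	T-	1309
nad4l	S_nigrivalveus	ATT	TAA	276
nad6	S_nigrivalveus	ATT	TAA	477
cob	S_nigrivalveus	ATG	TAG	1137
nad1	S_nigrivalveus	ATA	TAA	933
nad2	S_varius	ATA	TAA	978
cox1	S_varius	ATG	TAA	1536
cox2	S_varius	ATA	T-	682
atp8	S_varius	ATA	TAA	153
atp6	S_varius	ATG	TAA	654
cox3	S_varius	ATG	TAA	780
nad3	S_varius	ATT	TAA	354
nad5	S_varius	TTG	TAA	1668
nad4	S_varius	ATG	T-	1309
nad4l	S_varius	ATT	TAA	276
nad6	S_varius	ATA	TAA	480
cob	S_varius	ATG	TAA	1137
nad1	S_varius	ATT	T-	931
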