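##fileformat=VCFv4.2
##contig=<ID=chrA,length=5000>
##contig=<ID=chrB,length=3000>
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand">
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">
##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read pos rank sum">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4
chrA	100	.	A	T	50	PASS	QD=25.0;FS=1.2;MQ=59.8	GT	0/0	0|1	1/1	./.
chrA	250	.	A	AT	50	PASS	QD=20.0	GT	0/0	0/0	0/1	0/0
chrA	700	.	G	A,T	50	PASS	QD=18.0	GT	0/0	1/2	0/1	0/0
chrA	1200	.	C	G	50	PASS	QD=1.9;FS=2.0;MQ=55.0	GT	0/1	0/1	0/1	0/1
chrB	50	.	G	C	50	PASS	FS=60.0;MQ=40.0	GT	1|0	./1	0/0	1/1
chrB	2900	.	T	A	50	PASS	.	GT	0/0	0/0	0/1	0/1
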