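##fileformat=VCFv4.2
##source=hand-written-example
##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand bias (FisherStrand)">
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	mn1	mn2	nd1	nd2
u1	12	.	A	G	50	PASS	FS=1.5;QD=25;DP=120	GT:GQ	0/0:99	0/1:85	1/1:60	0/1:99
u1	45	.	C	T	50	PASS	FS=31.2;QD=25;DP=120	GT:GQ	0/0:99	0/0:99	0/1:99	0/1:99
u1	300	.	G	C	50	PASS	FS=2;QD=1.5;DP=90	GT:GQ	0/1:99	0/0:99	0/0:99	0/1:99
u2	7	.	T	A	50	PASS	FS=0.8;QD=30;DP=24	GT:GQ	0/1:99	./.:.	0/1:99	0/0:19
u2	60	.	T	TA	50	PASS	FS=1;QD=20;DP=100	GT:GQ	0/1:99	0/0:99	0/0:99	0/0:99
u2	61	.	G	A,T	50	PASS	FS=1;QD=20;DP=100	GT:GQ	1/2:99	0/0:99	0/0:99	0/0:99
u3	5	.	A	C	50	PASS	QD=20;DP=100	GT:GQ	0/1:99	0/1:99	0/0:99	0/1:99
u3	900	.	C	G	50	PASS	FS=3;QD=18;DP=200	GT:GQ	1/1:99	0/1:99	0/0:99	0/0:30
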