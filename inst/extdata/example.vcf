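##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012	S013	S014	S015	S016	S017	S018	S019	S020	S021	S022	S023	S024
chr2	10	v_mis	T	C	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr2	11	v_syn	T	C	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/1	1/1	1/1	0/0	0/0	0/1	0/1	0/1	0/1	0/0
chr2	21	v_stop	G	A	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr2	7	v_fs	TGG	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr2	48	v_misB	G	T	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
chr2	2	v_nc	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/0	0/1	0/0	0/0	0/1	1/1	1/1	0/0	0/0	0/1	0/0
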