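variant_id	drug_id	region_class	ethnicity
rsM00001	D003	noncoding	Asian
rsM00002	D015	noncoding	Caucasian
rsM00003	D019	noncoding	African-American
rsM00004	D013	noncoding	Asian
rsM00005	D006	noncoding	Caucasian
rsM00006	D009	noncoding	African-American
rsM00007	D005	noncoding	.
rsM00008	D011	noncoding	.
rsN00001	D018	noncoding	.
rsN00002	D001	noncoding	.
rsN00003	D002	noncoding	.
rsN00004	D012	noncoding	.
rs000049	D009	coding	.
rs000054	D019	coding	.
rs000010	D008	coding	.
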