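sample_id	population	superpopulation
S0001	pop_a	AFR
S0002	pop_a	AFR
S0003	pop_a	AFR
S0004	pop_a	AFR
S0005	pop_a	AFR
S0006	pop_a	AFR
S0007	pop_a	AFR
S0008	pop_b	EAS
S0009	pop_b	EAS
S0010	pop_b	EAS
S0011	pop_b	EAS
S0012	pop_b	EAS
S0013	pop_b	EAS
S0014	pop_c	EUR
S0015	pop_c	EUR
S0016	pop_c	EUR
S0017	pop_c	EUR
S0018	pop_c	EUR
S0019	pop_c	EUR
S0020	pop_c	EUR
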