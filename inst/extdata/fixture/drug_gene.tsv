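drug_id	gene_id	relation_type	atc_main_group
D001	G003	transporter	N
D002	G003	carrier	N
D002	G006	enzyme	N
D002	G011	target	N
D003	G006	transporter	J
D003	G010	transporter	J
D004	G006	carrier	D
D004	G007	carrier	D
D004	G005	transporter	D
D005	G003	transporter	R
D005	G004	transporter	R
D005	G002	target	R
D006	G007	enzyme	C
D006	G002	enzyme	C
D006	G005	transporter	C
D006	G010	transporter	C
D007	G004	target	V
D007	G006	target	V
D007	G001	enzyme	V
D008	G002	target	M
D009	G001	target	D
D010	G001	target	R
D011	G009	target	V
D011	G001	transporter	V
D011	G008	enzyme	V
D012	G003	carrier	J
D012	G001	target	J
D013	G002	transporter	M
D013	G008	carrier	M
D013	G005	enzyme	M
D013	G010	transporter	M
D014	G005	transporter	V
D014	G001	carrier	V
D014	G009	target	V
D015	G012	transporter	V
D015	G011	transporter	V
D016	G011	enzyme	P
D016	G008	transporter	P
D016	G010	carrier	P
D016	G006	target	P
D017	G004	enzyme	P
D017	G003	enzyme	P
D018	G005	enzyme	J
D018	G003	enzyme	J
D019	G005	carrier	L
D020	G006	target	A
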