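node	clade	t_L	t_M	root	c1_upper	c2_upper	c2_anomaly
91	Coccomorpha	140	240	TRUE	340	354	TRUE
79	Kuwaniidae	45	100	FALSE	155	50	FALSE
77	Ortheziidae	135	140	FALSE	145	149	FALSE
74	Putoidae	45	100	FALSE	155	50	FALSE
72	Pseudococcidae	135	140	FALSE	145	149	FALSE
64	Coccidae	98	110	FALSE	122	108	FALSE
50	Diaspididae	50	100	FALSE	150	55	FALSE
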