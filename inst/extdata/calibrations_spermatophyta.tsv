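node	clade	t_L	t_M	root	c1_upper	c2_upper	c2_anomaly
36	Spermatophytes	308.14	337	TRUE	366	339	FALSE
35	Angiosperms	125.9	186.5	FALSE	247	139	FALSE
31	Stem-Saururus	44.3	145.5	FALSE	247	48	FALSE
30	Acrogymnosperms	308.14	337	FALSE	366	339	FALSE
29	Ginkgo-Cycas	264.7	315.5	FALSE	366	282	TRUE
27	Conifers	147	229.5	FALSE	312	162	FALSE
20	Gnetales	119.6	216	FALSE	312	132	FALSE
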