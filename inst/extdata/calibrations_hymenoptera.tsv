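node	clade	t_L	t_M	root	c1_upper	c2_upper	c2_anomaly
111	Hymenoptera	235	302	TRUE	369	259	FALSE
108	Tenthredinoidea	140	234	FALSE	328	154	FALSE
79	Vespina	180	235	FALSE	290	198	FALSE
78	Apocrita	176	235	FALSE	294	194	FALSE
69	Siricoidea	161	235	FALSE	309	177	FALSE
63	Pamphiloidea	161	235	FALSE	309	177	FALSE
57	Xylidae	180	239	FALSE	298	198	FALSE
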