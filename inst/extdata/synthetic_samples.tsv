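sample_id	group	batch	p_low
s01	g1	b1	0.314362358067026
s02	g1	b1	0.140161415888883
s03	g1	b1	0.165285374478227
s04	g1	b1	0.17938535244316
s05	g1	b2	0.551466332944026
s06	g1	b2	0.552636002738595
s07	g1	b2	0.637406967014528
s08	g1	b2	0.594152238705642
s09	g2	b1	0.207632881314112
s10	g2	b1	0.309498905366469
s11	g2	b1	0.217849311516451
s12	g2	b1	0.335837589156536
s13	g2	b2	0.714072596299478
s14	g2	b2	0.616201027006926
s15	g2	b2	0.694803353340497
s16	g2	b2	0.623384025566085
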