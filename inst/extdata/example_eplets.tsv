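name	hla_class	confirmed
44KM	I	TRUE
62QE	I	TRUE
65RNA	I	TRUE
76ANT	I	TRUE
79GT	I	TRUE
90D	I	TRUE
138MI	I	TRUE
144KR	I	TRUE
163RG	I	TRUE
166DG	I	TRUE
62GE	I	TRUE
62GK	I	TRUE
107W	I	TRUE
127K	I	TRUE
144TKH	I	TRUE
145KHA	I	TRUE
150AAH	I	TRUE
161D	I	TRUE
151AHA	I	TRUE
163RW	I	TRUE
62EE	I	TRUE
65GK	I	TRUE
80I	I	TRUE
82LR	I	TRUE
62RR	I	TRUE
76ESI	I	TRUE
149TAH	I	TRUE
145RT	I	TRUE
56R	I	TRUE
65QIA	I	TRUE
69AA	I	TRUE
70IAQ	I	TRUE
76ESN	I	TRUE
80N	I	TRUE
163EW	I	TRUE
180E	I	TRUE
69TNT	I	TRUE
71TTS	I	TRUE
156DA	I	TRUE
41T	I	TRUE
44RMA	I	TRUE
80TLR	I	TRUE
131S	I	TRUE
144QL	I	TRUE
163LW	I	TRUE
44RT	I	TRUE
45KE	I	TRUE
163LS/G	I	TRUE
65QKR	I	TRUE
73TVS	I	TRUE
76VRN	I	TRUE
21H	I	TRUE
80K	I	TRUE
173K	I	TRUE
73AN	I	TRUE
138K	I	TRUE
177KT	I	TRUE
193PV	I	TRUE
163R	I	TRUE
158T	I	TRUE
219W	I	TRUE
9S	I	FALSE
17S	I	FALSE
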