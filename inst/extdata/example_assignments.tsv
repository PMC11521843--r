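allele	eplet	source
A*01:01	44KM	allele_eplet_listing
A*01:01	62QE	allele_eplet_listing
A*01:01	65RNA	allele_eplet_listing
A*01:01	76ANT	allele_eplet_listing
A*01:01	79GT	allele_eplet_listing
A*01:01	90D	allele_eplet_listing
A*01:01	138MI	allele_eplet_listing
A*01:01	144KR	allele_eplet_listing
A*01:01	163RG	allele_eplet_listing
A*01:01	166DG	allele_eplet_listing
A*01:02	44KM	allele_eplet_listing
A*01:02	62QE	allele_eplet_listing
A*01:02	65RNA	allele_eplet_listing
A*01:02	76ANT	allele_eplet_listing
A*01:02	79GT	allele_eplet_listing
A*01:02	90D	allele_eplet_listing
A*01:02	138MI	allele_eplet_listing
A*01:02	144KR	allele_eplet_listing
A*01:02	163RG	allele_eplet_listing
A*01:02	166DG	allele_eplet_listing
A*01:02	9S	allele_eplet_listing_unconfirmed
A*01:02	17S	allele_eplet_listing_unconfirmed
A*02:01	62GE	group_signature
A*02:01	62GK	group_signature
A*02:01	79GT	group_signature
A*02:01	107W	group_signature
A*02:01	127K	group_signature
A*02:01	144TKH	group_signature
A*02:01	145KHA	group_signature
A*02:01	150AAH	group_signature
A*02:05	62GE	group_signature
A*02:05	62GK	group_signature
A*02:05	79GT	group_signature
A*02:05	107W	group_signature
A*02:05	127K	group_signature
A*02:05	144TKH	group_signature
A*02:05	145KHA	group_signature
A*02:05	150AAH	group_signature
A*03:01	62QE	group_signature
A*03:01	65RNA	group_signature
A*03:01	79GT	group_signature
A*03:01	138MI	group_signature
A*03:01	144KR	group_signature
A*03:01	150AAH	group_signature
A*03:01	161D	group_signature
A*11:01	62QE	group_signature
A*11:01	65RNA	group_signature
A*11:01	79GT	group_signature
A*11:01	90D	group_signature
A*11:01	138MI	group_signature
A*11:01	144KR	group_signature
A*11:01	150AAH	group_signature
A*11:01	151AHA	group_signature
A*11:01	163RW	group_signature
A*24:02	62EE	group_signature
A*24:02	65GK	group_signature
A*24:02	80I	group_signature
A*24:02	82LR	group_signature
A*24:02	127K	group_signature
A*24:02	138MI	group_signature
A*24:02	144KR	group_signature
A*24:02	150AAH	group_signature
A*24:02	166DG	group_signature
A*25:01	62RR	group_signature
A*25:01	65RNA	group_signature
A*25:01	76ESI	group_signature
A*25:01	80I	group_signature
A*25:01	82LR	group_signature
A*25:01	90D	group_signature
A*25:01	138MI	group_signature
A*25:01	149TAH	group_signature
A*25:01	163RW	group_signature
A*26:01	62RR	group_signature
A*26:01	65RNA	group_signature
A*26:01	76ANT	group_signature
A*26:01	79GT	group_signature
A*26:01	90D	group_signature
A*26:01	138MI	group_signature
A*26:01	145RT	group_signature
A*26:01	149TAH	group_signature
A*26:01	163RW	group_signature
A*30:01	56R	group_signature
A*30:01	62QE	group_signature
A*30:01	65RNA	group_signature
A*30:01	79GT	group_signature
A*30:01	138MI	group_signature
A*32:01	62QE	group_signature
A*32:01	65RNA	group_signature
A*32:01	76ESI	group_signature
A*32:01	80I	group_signature
A*32:01	82LR	group_signature
A*32:01	138MI	group_signature
A*68:02	62RR	group_signature
A*68:02	65RNA	group_signature
A*68:02	79GT	group_signature
A*68:02	127K	group_signature
A*68:02	144TKH	group_signature
A*68:02	145KHA	group_signature
A*68:02	150AAH	group_signature
B*07:02	65QIA	group_signature
B*07:02	69AA	group_signature
B*07:02	70IAQ	group_signature
B*07:02	76ESN	group_signature
B*07:02	80N	group_signature
B*07:02	163EW	group_signature
B*07:02	180E	group_signature
B*08:01	69TNT	group_signature
B*08:01	71TTS	group_signature
B*08:01	76ESN	group_signature
B*08:01	80N	group_signature
B*08:01	156DA	group_signature
B*08:01	180E	group_signature
B*13:01	41T	group_signature
B*13:01	44RMA	group_signature
B*13:01	69TNT	group_signature
B*13:01	80TLR	group_signature
B*13:01	82LR	group_signature
B*13:01	131S	group_signature
B*13:01	144QL	group_signature
B*13:01	163EW	group_signature
B*15:01	69TNT	group_signature
B*15:01	71TTS	group_signature
B*15:01	76ESN	group_signature
B*15:01	80N	group_signature
B*15:01	131S	group_signature
B*15:01	163LW	group_signature
B*18:01	44RT	group_signature
B*18:01	69TNT	group_signature
B*18:01	71TTS	group_signature
B*18:01	76ESN	group_signature
B*18:01	80N	group_signature
B*18:01	131S	group_signature
B*27:01	65QIA	group_signature
B*27:01	69AA	group_signature
B*27:01	82LR	group_signature
B*27:01	131S	group_signature
B*27:01	163EW	group_signature
B*35:01	44RT	group_signature
B*35:01	69TNT	group_signature
B*35:01	71TTS	group_signature
B*35:01	76ESN	group_signature
B*35:01	80N	group_signature
B*35:01	131S	group_signature
B*35:01	163LW	group_signature
B*35:02	44RT	group_signature
B*35:02	69TNT	group_signature
B*35:02	71TTS	group_signature
B*35:02	76ESN	group_signature
B*35:02	80N	group_signature
B*35:02	131S	group_signature
B*35:02	163LW	group_signature
B*35:03	44RT	group_signature
B*35:03	69TNT	group_signature
B*35:03	71TTS	group_signature
B*35:03	76ESN	group_signature
B*35:03	80N	group_signature
B*35:03	131S	group_signature
B*35:03	163LW	group_signature
B*40:01	41T	group_signature
B*40:01	45KE	group_signature
B*40:01	69TNT	group_signature
B*40:01	71TTS	group_signature
B*40:01	76ESN	group_signature
B*40:01	80N	group_signature
B*40:01	163EW	group_signature
B*44:02	41T	group_signature
B*44:02	45KE	group_signature
B*44:02	69TNT	group_signature
B*44:02	80TLR	group_signature
B*44:02	82LR	group_signature
B*44:02	131S	group_signature
B*44:02	163LS/G	group_signature
B*51:01	44RT	group_signature
B*51:01	69TNT	group_signature
B*51:01	80I	group_signature
B*51:01	82LR	group_signature
B*51:01	131S	group_signature
B*51:01	163LW	group_signature
C*01:02	65QKR	group_signature
C*01:02	73TVS	group_signature
C*01:02	76VRN	group_signature
C*01:02	80N	group_signature
C*02:02	21H	group_signature
C*02:02	65QKR	group_signature
C*02:02	80K	group_signature
C*02:02	163EW	group_signature
C*03:04	21H	group_signature
C*03:04	65QKR	group_signature
C*03:04	73TVS	group_signature
C*03:04	76VRN	group_signature
C*03:04	80N	group_signature
C*03:04	163LW	group_signature
C*03:04	173K	group_signature
C*04:01	65QKR	group_signature
C*04:01	73AN	group_signature
C*04:01	80K	group_signature
C*04:01	90D	group_signature
C*05:01	65QKR	group_signature
C*05:01	80K	group_signature
C*05:01	138K	group_signature
C*05:01	177KT	group_signature
C*06:02	65QKR	group_signature
C*06:02	73AN	group_signature
C*06:02	80K	group_signature
C*06:02	90D	group_signature
C*07:01	76VRN	group_signature
C*07:01	80N	group_signature
C*07:01	90D	group_signature
C*07:02	76VRN	group_signature
C*07:02	80N	group_signature
C*07:02	90D	group_signature
C*07:04	76VRN	group_signature
C*07:04	80N	group_signature
C*07:04	90D	group_signature
C*12:03	65QKR	group_signature
C*12:03	80N	group_signature
C*15:02	21H	group_signature
C*15:02	80K	group_signature
C*15:02	193PV	group_signature
C*16:01	65QKR	group_signature
B*39:01	158T	pair_inference
B*44:02	156DA	pair_inference
B*15:01	44RMA	pair_inference
B*35:02	82LR	pair_inference
C*03:04	193PV	pair_inference
C*03:04	219W	pair_inference
C*04:01	193PV	pair_inference
C*07:02	163LW	pair_inference
C*07:02	219W	pair_inference
C*07:01	65QKR	pair_inference
C*07:04	65QKR	pair_inference
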