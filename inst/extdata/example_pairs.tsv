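pair_id	locus	recipient_genotype	donor_genotype
1	A	A*02:01/A*03:01	A*02:01/A*30:01
2	A	A*02:01/A*68:02	A*01:01/A*02:01
3	A	A*02:05/A*32:01	A*03:01/A*24:02
4	B	B*35:03/B*44:02	B*35:03/B*39:01
5	B	B*35:01/B*56:01	B*35:01/B*44:02
6	B	B*07:02/B*35:02	B*15:01/B*44:02
7	C	C*04:01/C*07:02	C*07:02/C*15:02
8	C	C*07:01/C*07:04	C*03:04/C*07:01
9	C	C*04:01/C*07:02	C*03:04/C*05:01
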