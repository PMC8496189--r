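plate_id	sort_gate	condition	sequenced	low_read_count	low_actb
VZC00104	CD45+	Healthy	384	22	7
VZC00214	CD45+	Healthy	160	22	2
VZC00215	CD45+	Healthy	160	30	1
VZC00703	CD45+	SCI (0.5 h)	192	38	3
VZC00801	CD45+	SCI (2 h)	191	31	6
VZC00601	CD45+	SCI (6 h)	384	70	4
VZC00604	CD45+	SCI (24 h)	384	93	10
VZC00803	CD45+	SCI (36 h)	192	38	0
VZC00501	CD45+	SCI (3 d)	384	47	6
VZC00101	CD45+	SCI (7 d)	384	55	15
VZC00205	CD45+	SCI (7 d)	384	108	13
VZC00401	CD45+	SCI (21 d)	384	127	14
VZC00901	CD45+	SCI (90 d)	383	42	77
VZC01001	CD45+	SCI MD (7 d)	384	71	2
VZC01101	CD45+	SCI MD (21 d)	384	74	17
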