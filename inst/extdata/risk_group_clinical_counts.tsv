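endpoint	factor	level	n_low	n_high
OS	age	le60	78	76
OS	age	gt60	75	74
OS	surgical	microscopic	36	22
OS	surgical	macroscopic	99	118
OS	platinum	sensitive	89	37
OS	platinum	resistant	18	44
OS	grade	2	17	10
OS	grade	3	136	141
OS	stage	2	10	4
OS	stage	3	122	121
OS	stage	4	24	30
PFS	age	le60	66	68
PFS	age	gt60	60	59
PFS	surgical	microscopic	31	19
PFS	surgical	macroscopic	80	98
PFS	platinum	sensitive	92	35
PFS	platinum	resistant	12	50
PFS	grade	2	14	7
PFS	grade	3	113	118
PFS	stage	2	9	4
PFS	stage	3	104	101
PFS	stage	4	18	23
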