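line_id	total	het	generation
Lo7	3145	141	F7
Lo152	3133	128	F7
Lo225	3134	147	F7
P87	3148	151	F7:10
P105	3127	139	F6:9
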