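cdr	start	end
L1	25	36
L2	51	58
L3	73	82
H1	112	122
H2	137	154
H3	169	189
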