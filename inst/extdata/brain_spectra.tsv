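tissue	1	2	3
normal	0.151	0.155	0.175
ischemia	0.115	0.12	0.13
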