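tissue	20000	50000	1e+05
pomelo	0.083	0.105	0.129
cucumber	0.047	0.065	0.093
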