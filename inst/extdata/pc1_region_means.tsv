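region	sample	mean_pc1
R1	Ga	-0.0378
R2	Ga	-0.0263
R1	IL9	-0.0486
R2	IL9	-0.0357
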