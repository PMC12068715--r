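sample	chrom	size_mb
AL11	Chr11	0.61
IL11	Chr11	0.36
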