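sample	chrom	start_mb	end_mb
Ga	Chr09	45.67	46.71
AL9	Chr09	45.91	46.67
IL9	Chr09	46.04	46.69
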