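target	effect	t_start	t_stop
MK6	-1	1	96
GRD	-1	7	93
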