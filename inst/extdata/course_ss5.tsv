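target	effect	t_start	t_stop
TEST	1	1	43
CK1	-1	21	83
GRD	-1	75	99
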