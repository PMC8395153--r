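	SS0	SS1	SS2	SS3	SS4	SS5
Stress	0	0	0	0	0	0
Toxin	0	0	0	0	0	0
CRH	0	0	0	0	0	0
ACTH	0	-1	0	0	0	0
CORT	0	0	1	1	1	1
GR	0	1	1	1	1	1
GRD	0	1	1	1	1	1
GnRH	0	0	-1	-1	-1	-1
LHFSH	0	0	-1	-1	-1	-1
TEST	0	0	-1	-1	-1	-1
NK	0	0	-1	-1	-1	-1
CTL	0	0	0	1	1	1
Th1	0	0	0	0	-1	0
Th2	0	0	1	0	0	0
Th17B	0	0	1	0	1	1
Th17_23	0	0	1	0	1	1
Treg	0	0	-1	1	0	0
DC	0	0	-1	0	0	0
CK1	0	0	0	1	1	1
CK2	0	0	1	0	0	0
CK17	0	0	1	0	1	1
MK1	0	0	1	0	1	1
MK2	0	0	1	1	1	1
MK6	0	0	1	0	1	1
MK15	0	0	-1	0	1	1
MK21	0	0	1	0	1	0
MK23	0	0	-1	0	0	0
MK27	0	0	-1	0	0	0
TGFb	0	0	0	0	-1	0
EndothelialCells	0	0	1	1	1	-1
Microglia	0	0	0	0	0	1
ProInflam_b	0	0	-1	1	0	1
IL4_b	0	0	1	-1	1	0
Tcell_b	0	0	1	1	1	0
IGF1	0	0	-1	-1	0	0
VEGF	0	0	0	0	0	1
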