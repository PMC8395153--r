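# ternet network file
node	Stress	external
node	Toxin	external
node	CRH	hpa
node	ACTH	hpa
node	CORT	hpa
node	GR	hpa
node	GRD	hpa
node	GnRH	hpg
node	LHFSH	hpg
node	TEST	hpg
node	NK	immune-cell
node	CTL	immune-cell
node	Th1	immune-cell
node	Th2	immune-cell
node	Th17B	immune-cell
node	Th17_23	immune-cell
node	Treg	immune-cell
node	DC	immune-cell
node	CK1	cytokine-group
node	CK2	cytokine-group
node	CK17	cytokine-group
node	MK1	cytokine-group
node	MK2	cytokine-group
node	MK6	cytokine-group
node	MK15	cytokine-group
node	MK21	cytokine-group
node	MK23	cytokine-group
node	MK27	cytokine-group
node	TGFb	cytokine-group
node	EndothelialCells	brain
node	Microglia	brain
node	ProInflam_b	brain
node	IL4_b	brain
node	Tcell_b	brain
node	IGF1	brain
node	VEGF	brain
edge	Stress	CRH	activate
edge	CRH	ACTH	activate
edge	MK6	ACTH	activate
edge	CK1	ACTH	activate
edge	GR	ACTH	inhibit
edge	ACTH	CORT	activate
edge	MK6	CORT	activate
edge	CK1	CORT	activate
edge	GRD	GR	activate
edge	CORT	GR	activate
edge	GR	GRD	activate
edge	CORT	GRD	activate
edge	CORT	GnRH	inhibit
edge	Treg	GnRH	inhibit
edge	GnRH	LHFSH	activate
edge	LHFSH	TEST	activate
edge	CORT	NK	inhibit
edge	CORT	MK2	activate
edge	CK1	CTL	activate
edge	MK2	CTL	activate
edge	DC	CTL	activate
edge	CK2	CTL	inhibit
edge	CTL	CK1	activate
edge	MK6	Th2	activate
edge	MK2	Th2	activate
edge	CK1	Th2	inhibit
edge	NK	Th2	inhibit
edge	Th2	CK2	activate
edge	Stress	CK2	activate
edge	MK2	Th17B	activate
edge	Treg	Th17B	inhibit
edge	NK	Th17B	inhibit
edge	TEST	Th17B	inhibit
edge	Th17B	Th17_23	activate
edge	Th17B	CK17	activate
edge	Th17_23	CK17	activate
edge	CK17	MK1	activate
edge	Th17B	MK6	activate
edge	Th17B	MK21	activate
edge	ProInflam_b	MK21	inhibit	EndothelialCells=-1
edge	CK1	Treg	activate
edge	CK17	Treg	inhibit
edge	Stress	Treg	inhibit
edge	CK1	MK15	activate
edge	CK2	MK15	inhibit
edge	Treg	MK15	inhibit
edge	CK2	MK23	inhibit
edge	CK2	MK27	inhibit
edge	CK2	DC	inhibit
edge	CK2	TGFb	activate
edge	MK21	TGFb	inhibit
edge	TGFb	Th1	activate
edge	CK2	EndothelialCells	activate
edge	Tcell_b	EndothelialCells	activate
edge	Microglia	EndothelialCells	inhibit
edge	CTL	Tcell_b	activate
edge	Th2	Tcell_b	activate
edge	Microglia	Tcell_b	inhibit
edge	Stress	Microglia	activate
edge	Toxin	Microglia	activate
edge	MK1	Microglia	activate	EndothelialCells=-1
edge	MK15	ProInflam_b	activate
edge	IL4_b	ProInflam_b	inhibit
edge	CK2	IL4_b	activate
edge	MK15	IL4_b	activate
edge	Treg	IL4_b	inhibit
edge	Microglia	IL4_b	inhibit
edge	MK15	IGF1	activate
edge	Tcell_b	IGF1	inhibit
edge	Microglia	IGF1	inhibit
edge	Microglia	VEGF	activate
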