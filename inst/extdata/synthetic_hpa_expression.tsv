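Tissue	Cluster	Gene name	nTPM
skin	c-0	CD3E	52.0
skin	c-0	KRT14	1.5
skin	c-0	PECAM1	0.8
skin	c-1	CD3E	46.0
skin	c-1	KRT14	2.1
skin	c-1	PECAM1	1.2
skin	c-2	CD3E	1.0
skin	c-2	KRT14	58.0
skin	c-2	PECAM1	0.5
skin	c-3	CD3E	0.4
skin	c-3	KRT14	1.1
skin	c-3	PECAM1	47.5
lung	c-9	CD3E	99.0
lung	c-9	KRT14	99.0
lung	c-9	PECAM1	99.0
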