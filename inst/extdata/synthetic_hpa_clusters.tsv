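Tissue	Cluster	Cell type	Cell count
skin	c-0	T-cells	120
skin	c-1	T-cells	40
skin	c-2	basal keratinocytes	300
skin	c-3	endothelial cells	90
lung	c-9	macrophages	10
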