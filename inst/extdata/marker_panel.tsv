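cell_type	gene	direction
stromal_core	VIM	positive
stromal_core	HLA-A	positive
macrophage	CD14	positive
macrophage	CD68	positive
mesenchymal	CD90	positive
blood	HBB	positive
trophoblast	CK7	positive
trophoblast	TFAP2C	positive
trophoblast	GATA3	positive
CTB	CDH1	positive
CTB	EGFR	positive
CTB	HLA-G	negative
EVT	HLA-G	positive
EVT	MMP2	positive
STB	CGB	positive
STB	CSH1	positive
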