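gene	class	source
PHLDA2	maternally_expressed	geneimprint
CDKN1C	maternally_expressed	geneimprint
ZNF331	maternally_expressed	geneimprint
PHACTR2	maternally_expressed	geneimprint
TFPI2	maternally_expressed	geneimprint
PPP1R9A	maternally_expressed	geneimprint
ANO1	maternally_expressed	geneimprint
RHOBTB3	paternally_expressed	geneimprint
PEG3	paternally_expressed	geneimprint
PEG10	paternally_expressed	geneimprint
MEST	paternally_expressed	geneimprint
MEST1	paternally_expressed	geneimprint
GRB10	maternally_expressed	geneimprint
ASCL2	maternally_expressed	geneimprint
H19	maternally_expressed	geneimprint
GPR1	paternally_expressed	geneimprint
IGF2	paternally_expressed	geneimprint
KCNQ1OT1	paternally_expressed	geneimprint
MEG3	maternally_expressed	geneimprint
PLAGL1	paternally_expressed	geneimprint
DLK1	paternally_expressed	geneimprint
NNAT	paternally_expressed	geneimprint
NDN	paternally_expressed	geneimprint
SNRPN	paternally_expressed	geneimprint
MKRN3	paternally_expressed	geneimprint
MAGEL2	paternally_expressed	geneimprint
GNAS	complex	geneimprint
NAP1L5	paternally_expressed	geneimprint
OSBPL5	maternally_expressed	geneimprint
SLC22A18	maternally_expressed	geneimprint
CD81	maternally_expressed	geneimprint
ZIM2	paternally_expressed	geneimprint
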