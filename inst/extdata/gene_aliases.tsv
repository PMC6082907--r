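alias	symbol
CK7	KRT7
CD90	THY1
CD105	ENG
E-cadherin	CDH1
Syncytin-2	ERVFRD-1
PAI-1	SERPINE1
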