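gene	class	source
CGA	glycoprotein_hormone	literature
CGB	glycoprotein_hormone	literature
CGB1	glycoprotein_hormone	literature
CGB2	glycoprotein_hormone	literature
CGB5	glycoprotein_hormone	literature
CGB7	glycoprotein_hormone	literature
CGB8	glycoprotein_hormone	literature
CSH1	somatotropin	literature
CSH2	somatotropin	literature
CSHL1	somatotropin	literature
GH2	somatotropin	literature
INSL4	insulin_like	literature
PSG1	pregnancy_specific_glycoprotein	literature
PSG2	pregnancy_specific_glycoprotein	literature
PSG3	pregnancy_specific_glycoprotein	literature
PSG4	pregnancy_specific_glycoprotein	literature
PSG5	pregnancy_specific_glycoprotein	literature
PSG6	pregnancy_specific_glycoprotein	literature
PSG7	pregnancy_specific_glycoprotein	literature
PSG8	pregnancy_specific_glycoprotein	literature
PSG9	pregnancy_specific_glycoprotein	literature
PAPPA	metalloproteinase_hormone_axis	literature
PAPPA2	metalloproteinase_hormone_axis	literature
TAC3	tachykinin	literature
FSTL1	follistatin_like	literature
FSTL3	follistatin_like	literature
ANGPTL1	angiopoietin_like	literature
ANGPTL2	angiopoietin_like	literature
ANGPTL4	angiopoietin_like	literature
CTGF	matricellular	literature
ACTN1	matricellular	literature
INHBA	activin_inhibin	literature
LEP	adipokine	literature
CRH	releasing_hormone	literature
ADM	vasoactive_peptide	literature
EDN1	vasoactive_peptide	literature
NPPB	natriuretic_peptide	literature
KISS1	kisspeptin	literature
GDF15	tgf_beta_family	literature
PTHLH	parathyroid_related	literature
RLN2	relaxin	literature
VGF	neurosecretory	literature
IGF2	insulin_like	literature
GNRH1	releasing_hormone	literature
POMC	proopiomelanocortin	literature
OXT	neurohypophyseal	literature
AVP	neurohypophyseal	literature
TRH	releasing_hormone	literature
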