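id	name	compartment	role
lpsA[e]	LPS-like ligand A	e	ligand
rnaB[e]	ssRNA-like ligand B	e	ligand
dnaC[e]	CpG-DNA-like ligand C	e	ligand
orphan1[e]	orphan ligand 1	e	ligand
orphan2[e]	orphan ligand 2	e	ligand
sigA[c]	receptor A proximal signal	c	receptor
sigB[c]	receptor B proximal signal	c	receptor
sigC[c]	receptor C proximal signal	c	receptor
adap[c]	activated adaptor	c	protein
kin1[c]	activated kinase 1	c	kinase
kin2[c]	activated kinase 2	c	kinase
tfNFKB[c]	active NF-kB	c	complex
tfAP1[c]	active AP-1	c	complex
tfCREB[c]	active CREB	c	complex
tfIRF[c]	active IRF	c	complex
nfkb[n]	nuclear NF-kB	n	complex
ap1[n]	nuclear AP-1	n	complex
creb[n]	nuclear CREB	n	complex
irf[n]	nuclear IRF	n	complex
ros[v]	reactive oxygen species	v	metabolite
atp[c]	ATP	c	metabolite
adp[c]	ADP	c	metabolite
gtp[c]	GTP	c	metabolite
gdp[c]	GDP	c	metabolite
loopx[c]	loop intermediate X	c	protein
loopy[c]	loop intermediate Y	c	protein
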