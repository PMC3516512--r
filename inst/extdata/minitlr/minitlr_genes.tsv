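gene_id	symbol	description
101	TLRA	receptor A
102	TLRB	receptor B
103	TLRC	receptor C
104	TLRO1	orphan receptor 1
105	TLRO2	orphan receptor 2
201	ADAP1	adaptor isozyme 1
202	ADAP2	adaptor isozyme 2
301	KINA1	kinase-1 isozyme 1
302	KINA2	kinase-1 isozyme 2
303	KINA3	kinase-1 isozyme 3
401	KINB1	kinase-2 subunit 1
402	KINB2	kinase-2 subunit 2
501	NFKB1	NF-kB activator
502	FOSL	AP-1 subunit Fos-like
503	JUNL	AP-1 subunit Jun-like
504	CREB1	CREB activator
505	IRFL	IRF-like factor
601	PHOXA	oxidase subunit A
602	PHOXB	oxidase subunit B
701	LOOPG	loop enzyme
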