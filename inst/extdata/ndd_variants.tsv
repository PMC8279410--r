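# Literature catalog of NDD-associated MTOR missense variants (33 rows).
# Phenotype evidence flags: sks = Smith-Kingsmore syndrome, fcd = focal
# cortical dysplasia 2a/2b, mega = asymmetric megalencephaly/polymicrogyria/
# cutaneous pigmentary mosaicism group. hgvs_c carried as opaque metadata.
hgvs_c	hgvs_p	sks	fcd	mega	domain	interface
c.1871G>A	p.R624H	0	1	0	N-Heat	
c.4169G>A	p.C1390Y	1	0	0	FAT	
c.4184A>G	p.K1395R	1	0	0	FAT	FAT Hinge
c.4348T>G	p.Y1450D	0	1	0	FAT	FAT Hinge
c.4487T>G	p.W1456G	0	1	0	FAT	FAT Hinge
c.4376C>A	p.A1459D	0	1	0	FAT	FAT Hinge
c.4375G>T	p.A1459S	0	1	0	FAT	FAT Hinge
c.4379T>C	p.L1460P	0	1	0	FAT	FAT Hinge
c.4447T>C	p.C1483R	0	1	0	FAT	FAT Hinge
c.4448G>T	p.C1483F	1	0	0	FAT	FAT Hinge
c.4448C>T	p.C1483Y	0	0	1	FAT	FAT Hinge
c.4468T>C	p.W1490R	1	0	0	FAT	FAT Hinge
c.4785C>T	p.M1595I	1	0	0	FAT	
c.5005G>T	p.A1669S	0	0	1	FAT	
c.5126G>A	p.R1709H	0	1	0	FAT	FAT Hinge
c.5395G>A	p.E1799K	1	0	0	FAT	N-lobe C-lobe Interface
c.5494G>A	p.A1832T	1	0	0	FAT	
c.5663A>C	p.F1888C	1	0	0	FAT	N-lobe C-lobe Interface
c.5930C>G	p.T1977R	0	1	0	FAT	FAT-N-lobe Interface
c.5930C>T	p.T1977I	0	0	1	FAT	FAT-N-lobe Interface
c.5930C>A	p.T1977K	0	1	1	FAT	FAT-N-lobe Interface
c.6577C>T	p.R2193C	0	1	0	Kinase N-Lobe	
c.6605T>G	p.F2202C	1	0	0	Kinase N-Lobe	N-lobe C-lobe Interface
c.6644C>A	p.S2215F	0	1	1	Kinase N-Lobe	N-lobe C-lobe Interface
c.6644C>T	p.S2215Y	0	1	1	Kinase N-Lobe	N-lobe C-lobe Interface
c.6981G>A	p.M2327I	1	0	0	Kinase C-Lobe	ATP Binding Site
c.7216G>A	p.V2406M	1	0	0	Kinase C-Lobe	N-lobe C-lobe Interface
c.7235A>T	p.D2412V	1	0	0	Kinase C-Lobe	N-lobe C-lobe Interface
c.7280T>A	p.L2427Q	0	1	0	Kinase C-Lobe	ATP Binding Site
c.7280T>C	p.L2427P	0	1	0	Kinase C-Lobe	ATP Binding Site
c.7498A>T	p.I2500F	1	0	0	Kinase C-Lobe	
c.7501A>G	p.I2501V	1	0	0	Kinase C-Lobe	
c.7570C>A	p.Q2524K	1	0	0	FATC	
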