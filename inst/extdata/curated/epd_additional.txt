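# Proteins added to the KPs to form the Experimental Prionogenic Domain (EPD) set:
# prionogenic by SUP35C fusion assay plus in vivo amyloid evidence
# accession<TAB>gene
P14907	NSP1
P18494	GLN3
P32588	PUB1
P32770	NRP1
P38180	YBL081W
P38216	YBR016W
P38429	SAP30
P38691	KSP1
P40070	LSM4
P40356	PGD1
P53894	CBK1
Q05166	ASM4
Q08925	MRN1
Q12139	YPR022C
Q12221	PUF2
Q12224	RLM1
Q12361	GPR1
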