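# Experimental Prion Negatives (EPN): failed all prion-activity assays
# accession<TAB>gene
P11746	MCM1
P14680	YAK1
P22082	SNF2
P23291	YCK1
P25339	PUF4
P32505	NAB2
P32896	PDC2
P32900	SKG6
P38080	AKL1
P39081	PCF11
P43572	EPL1
P45978	SCD6
P53617	NRD1
P53829	CAF40
Q03761	TAF12
Q05785	ENT2
Q06251	YLR177W
Q12124	MED2
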