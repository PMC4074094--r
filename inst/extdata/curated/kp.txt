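# Known Prions (KP): well-characterized amyloid-based yeast prions
# accession<TAB>gene
P05453	SUP35
P07884	MOD5
P09547	SWI1
P14922	CYC8
P23202	URE2
P25367	RNQ1
P32432	SFP1
Q08972	NEW1
P54785	MOT3
Q02629	NUP100
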