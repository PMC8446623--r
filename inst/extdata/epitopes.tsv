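name	peptide	note
DQ2.5-glia-a1a	PFPQPQLPY	DQ2.5-restricted 9-mer, repeat domain
DQ2.5-glia-a1b	PYPQPQLPY	DQ2.5-restricted 9-mer, repeat domain
DQ2.5-glia-a2	PQPQLPYPQ	DQ2.5-restricted 9-mer, repeat domain
DQ2.5-glia-a3	FRPQQPYPQ	DQ2.5-restricted 9-mer
33mer	LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF	33-residue immunotoxic fragment containing six overlapping epitopes
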