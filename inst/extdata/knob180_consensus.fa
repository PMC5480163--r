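>knob180 Zea knob satellite consensus monomer, 180 bp, circular
TGGGGTGAGGTGTATGAGCCTCTGGTCGATGATCAATGGCCACACAACCCCCATTTTTGT
CGAAAATAGCCATGAACGACCATTTTCAATAATACCGAAGGCTAACACCTACGGATTTTT
GACCAAGAAATGGTCTCCACCAGAAATCCAAGAATGTGATCTATGGCAAGGAAACATATG
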