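>CentC Zea centromeric satellite consensus monomer, 156 bp, circular
TGGTTCCGGTGGCAAAAACTCGTGCTTTGTATGCACCCCGACACCCGTTTTCGGAATGGG
TGACGTGCGGCAACGAAATTGCGCGAAACCACCCCAAACATGAGTTTTGGACCTAAAGTA
GTGGATTGGGCATGTTCGTTGCGAAAAACGAAGAAA
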