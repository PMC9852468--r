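>SYN1 synthetic 240-bp amplicon, protospacer at 100, cut near center
TACTCCGTCTAATTTCGCATGGTGCCCCGACTTCCATAGCCCTTAAGGTTCCATGAGATAACCAAATAGACGGGCGGCGGACAGCCAAGGCTTCAAGAATGACGTTCTCGATGGTGCTAGCGGCGCGTGTACACTCGACCCCCTTACCGGCCTATCCACTTGCCTGAAGGGCACATCAGTACATTTTTCATTGCCCAGATCGTTAGAATCATATCCGTTTAACACGTGGTGGGTCCCACC
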