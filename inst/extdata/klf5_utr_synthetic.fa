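>KLF5_UTR_synthetic synthetic stand-in 3-UTR; 7mer-A1 site planted at nt 482-488
AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC
AGCAATCTTGCATCATTGTTATCGAACGGAGCCGGTATGAAGTACAGGACGTTGGGCAAG
ATACCATGGCAAGTGCCTGGCGAAGGACGTTAAGTTTGAGGAAAGCACAAACGTACCATC
CAAGGACTGGTGCTTGCGTGAACCTAACCATTTTTCCGACGACTTGGTCGATTTAGTTAC
AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACCTAGGCTCCAAGC
GATAGCTACAGAGCAAGGCTCAACGCCATGGATATCGGCGCCAATCCACAGATGATGACC
TGACGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCATGCGCTATAC
GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG
TGAACAAATGCTATGTGTCTATGTTCGAGGCTGCTTTCGTTATTACTTGAAGTTAGTATG
AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA
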