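>IGKV1-5*01
GCCGAGACCCCTGCTGGGTCGTCACGGGCGCAACCCAGTAAACGCCGCCCAGCATATGGGGGAAAAACGCCACGGGTCATCCGTCGATCAGCTGATAGGAGTGACTTATTCATGTAGAGCTTTTCGACAACCCTCTGGTCGTATCGCGATAGCTTTCACAACTTTCGTACATTAGTTCTAGCCACCAGGGTTATTGAGCAGGACCGTTGCTGGCGGCGTGCAGGTATGGCCGCGAGCGTCGGGTAAATAAAGAAACCGGTGGGGTGAGTGTGTCAACAGTATAATAGTTAT
>IGKV1-9*01
ACTCTAACGTGGAACGTACCTCAGGCTGCGCTGGAAAAAACGGGCGGTACTGAATTTTGGCCATTCTGAAGGGCCCGGATGCCGCCGGTGGCAGTAGAGGTGCCTGCTGCATGAGTCCGTCGGGCAGGAAGTGGGGGTCGAAAGCATACAGCGCTCCAGGCATATGGGAAATGCTATCCGCAATGCCGTGTCGCTATCGGCATCTAGAGGAGAATCGGATAACGTCGGCCACAAACCGCGAGTAGCTCTTGGCCCTGCTCGACTCGCTCACTGTGTCAACAGTATGATAATCTT
>IGKV1-33*01
ACAATTCCGCGCCCTCGCTCGAGGAGTATAGGAAGTAGCACGCGCGGGTATACCAGGACCTCGCCGAAGGCTCGAATACCCAGCTACCCCAGACCCAATGCCCGAGAATTGGACTAATGGTCCACCAGGATGCGAAGCGAGCGCAATCGTCCTAGCAAACGAGCAGCGACCGAAACACTCCAGCTGTGCGGGGAGTGTAATTTCACCCAAGGGTGCAAAGGCGCCGATGTAATGGTCCTGCAGCGTGTACGGCCGAAGTACGACGAATCGTGTCAACAGTATGATAATTTA
>IGKV1-39*01
ACGTTTGCTACGTGTCCGCCAGATTGTGAGCGCTACCAGTCTGATGATAATAGCCAGAGAAAGTTTAAATAGCGACGGGGGGTTCCGTTACGATTCCGTTCCACTATGACCTTTCCGATCATACACACCGTAAGCGCTAACTCTGAGCATGCCTCCCGCGCATCGGACCGACGTTCAAATGACGGGTAGCAACGGACGAGCCCCCCTACCATCATTAGGCGAGTGGTGTTCCGCAATGGCCGAATGATTGCGTCTGTTTCCCCGACTGCCCACGAGTGTCAACAGAGTTACAGTACT
>IGKV2-24*01
CTAGACTGAAGGGTTGGAATGGTCTGGCGGAATGCGTTTGGACGATAGCGGGAGTGGCCTATTTAGCCTAATCTCGTAATGTCGATGCGCGCGAGCTGTGCAACAACCCTGAGCCGCCTATCGATCGGCTAAGTTGCCAGGCGGGCTTCAAGCAGCCCATGACTGTGGGCGAGGCGGGGACGCACCGCTTCGACCTCAGCTCCTGGGCGGCAGAAGGTTTGCATTCGTGTATAGACATGAATCATGAGCCTGTCAAAATGTGATGCGGCTTCGGTCCCATGTCAACAATATAATAGTTAC
>IGKV2-28*01
CGGGGCGCAGCCTGACCACACCGGTGCCGACTGTGATCAGCTGGCTGCCCCCGGTCAGCTGGTTCCCAAGCGACCGCGCCCGCATAACTCTCTCTTACTTACAGGCCACTTGTGATACAACCAGCCGCTACTTGGATAGCCCATGTGTCACGTATAGTTAGCGCATGGCACGGGCCGACGACATTCCTTGATCGATTCAGAAGCTAGGAAGTGCGTGACTGAACGGACGCTTGGCTAGACGCCTTACAAAATAGCCCGCAACGCCGCTGTTAGGCGTGTATGCAAGCTCTACAAACT
>IGKV2-30*01
ACGCAGCGCACCAGGCCATTGATTCAACTGCGCACCCAATAGGGCCCGACTTGGCCCCAATGAGTTACGTGATTCTTTTCAGCCAGGTGGCATCGAGCCAGAAGCGGACGCGGACCTGGCGTCGTTCCACGTGGGTTTAACTTTGTCGGGGGATTGAATGGTGCTCGGATGGTCCGAGGGACGACGCTGGATTGTATCTAGTTTGGGCTAGCGTATTCGTCTTCCAATTATGCAAAAAACCGATGCCGTCACCTACCGCCCATTCCCCCCATTTGTATGCAAGGTACACACTGG
>IGKV3-11*01
GTAGAATCAGAAGAGACGGCTAATACTCTGCGTTAACGTTTCTAACGCCACGCGACTCCGGACTATCAGTGACCACTCCCCTTCTTCCTGCGGAAACAGACGTCAAAGGTAGTGTAGCACCGGCAAAAGGTAATATGGCGCCCATGGCCAGTTCCCCGATGACAACGCACTATACGGCAACGATCCGCTAAAGCCTCGATTTGTTAATAGCGCCGATGCTCGTCGGCCCGTCAATACCCGTTTACGGGAACTTACCGTCCCTTCAGGTCTTGTCAGCAGCGTAGCAACTGG
>IGKV3-15*01
CCGCCTCAAGGCCGTCCCCCGGATCTGCCAGCAACCTGTTCGGTTTCGGGAGCGTCCGAAGCACGCTTTGGTGTTCGGGATCCCATTAATCTACAGAATTAGCCTATAGAGCTAGAATTAGCGGATTATCTGGCTAGGTCATCCCAAGTTCGGGCGTCGCGGGGTGTCGGAAGTCCGTCCGCACTTCCCTCCACATGCCTAACAGAGCGATTCTATCTCTTCAAAGGGTCGCGAAACGGGAAATAACTACTCGTCGTTGCGCGCCAGGAGGAGTATTGTCAGCAGTATAATAACTGG
>IGKV3-20*01
GAGTATAGTCCCCCGCTCAAGGTCACATAGCGCCTGCGAGTTTAAACCGGAGATACACGCCTGGACGCCGCAGGGGCAGTTCACTCACTTAGATTACCATCTTGACATGCAGGACTAGCAAGGCCACCTGCGCTAACCCCGGGGGTGATTAGGAAGTAAAAAATCGGGCTGGCATATTTGTAGCGCCTCTGGGACGTACCCTTTTTCGAGTCTAGCGGGGCGGTCCTCCCCAACATATAGAGGGCACGGCGTGGCTAGCGCCTCGAGAGACGGTGTCAGCAGTATGGTAGCTCA
>IGKV4-1*01
TCACGCCCTATTCCACGTGGGGCCTTGGGGTGGTCGGTTGGCGACCTGGGTGAGGGCTCTCGCCGGGCGGCGCGCTAGTTTTGGCGGACGCACTGCGAGGGAGCGCTCGGTCTGGACACGGCTACGAAGGGCAGCGGACCGCACCGCTTCAAGCCACCCAAAGGCGGTACACCATCGTACAAGCCAGCGCCGCATAAATGGAACCCAGCTATTTTCCGCCGGCGTGGGAAGCGAGTAAGGCCACGGTAGCTAGTCTGATCCTGGCCCGAACGAGTGTCGCATTGTCAGCAATATTATAGTACT
>IGKV5-2*01
GAGTGATCACCTCTTTTAGCTTTCGACGCTAGCCCCCCACCTGAGGTCCGACGAGCTCGTCTCTCCTTATCAACCCGTAGGTAACGCGTGGCACCCCGTGCCCGTGCCAAAACACGGGACATTGCAACGAAGTAGATTCTAAATTCTAAAACCGCAACGAGGGGCTAGGAACCGTCACGGTTCCCAGGCTTCCGCGACCTCCCCTCTGTAATGCCGACTCGTTCCCAGTACCCGCGTCTGCAGGGATCTACATTAAAAACCGTGTCCGCATGTCAACAGTATAGTAGTTCT
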