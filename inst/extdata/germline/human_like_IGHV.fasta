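>IGHV1-2*01
CGAGTAACATATTGAGGGCCATTCGCTGGCCATTATAGCCAACTATGGCTGTGGAGTTATAGCAAGGGCTGCCCGGCCATAGACGTGATGCTACCGGGCTATCCGATTTGGCTGACGCATTGGCGGCCCGGGAAAGAAGCAAGGCCGGAGCATACTGGGGGCGCGGGTACTCTGGAAGGAGCGCGAGGGGGAGGGGCTCGACAGCGCTAGACCTTCGTGAAATATCAGCGGTACGCGCGACCACTTGTCCAACCATATGAGCAGTAACGCGCTATGGATCGATGTGCGAGAGAT
>IGHV1-18*01
AGAGGAGAGATTGTACCTGCTCGGATTCGGTAAACGATCGAACTCAGGTATCGTAGCGCCTGAGCGAACCCGTAAGCATAGTAGCCGCAACATACAAGGGGAGACCAGCCAGAGATTCTCCTGCAATGCACCGTGCCGTAGGTCAACGGGCTGACTACGGATACGCGGGGATGTCGCTAGAGCAGATCAGGGCCGTCCGTAGCCTGCGGTTTTCGTGAGTAAAGAGTTAAGAGCCCACATTCATTACCACAGCTTAACCTGCGTTGCATCGGTTTATGCGTACCGTGTGCGAGAGGT
>IGHV1-69*01
CGATGGGTCTCCAGGAGGGCGCCCATCAAGAGGGCAACATGAATAGGTCGTCAGGTGTGCTCCGTGGAGACTGAAAGCGAACCTACAGAGACTGACGCATAGCCACCGCTTCAGCAAAGGACCCCAGCAAAGTTTACCGCCTTGCGTCACGCGCGTATCACACGTCCTAGCACAGGCAGAATCGGCATACCCATCGCCACCGAGCACGCTAAGACCGCTAAGAGGGCTAGGAAAGCCCGTGACACACTTCGCAGCGGTCTTGCGGCTAGTTAGAGGGGCGTTGAAGTGTGTGCGAAAGAT
>IGHV2-5*01
CCTCGATATGCCGGCTGAGGATAGACCCGATGCAAAGCGCTCTCGCGCCAGATTGCTAGGACGTGAGGTACTCGGGGTGTTCGGGGGAGTCCGTGACACAAGTAGACCGAACGGGGATGAGCTTCGGCGGAGGTGCCACTGACGAGCACGGGCCGCACCCGCCTGCCACGAAAACGTAGCCGCCCATCCCTGAGATCTGGTTCTAAGGTAGAATTCGCGGGCATCTTCGGGCATGAATAGCGCACGACAGCCTTGTGGACCATGTGACACTGACACTGTTGTGCCAGAGAC
>IGHV3-7*01
CCGACCGAGCGTTACACGTGGTGCAATCGATGCACGGCGTGTTACAATCGGGCACCACCTCCAGTTATTTCCGCTTTCTGGTGCTATGGTCTCCCCGGCTAAGGGCTCTGGGGCTGTCAACTAGCGAGGGTCTTGGAGGAGTCGCCCGGAGCGTCCAGGCGGAAGCGCATAAGGGCGGTTGCGAGGCTATGGTCCCCCGTGGGGAGGCGGGACCTTGGCACGATATGCCTGTTCGGGATCTATCTTGTCGCGGGGGTGACAAGAGGGGCCGACGATCCGCTCTGTGCGAAAGAC
>IGHV3-23*01
TCCCCATGTCAACGGGCCCGAGATCCTCCAGCCTAGCAGAAGGGAGCGGCCCCTCCGACGGACATACCTATTGCTTGCCGGCCGGGTTATTTATAACCTGCGGCATCAGAACCGCAGTAGTTCGCAGTCTCGACACGGGATTTAGGTGGGTACTAGCTAGCAAGGCGGAGAGTGGCAGCGCCAGAAACGTGCATTAGATACAAGGACCGAACGCCGCAAAACGATGCCAGAGCATAGTCGGGGACACGGCGGGGCGGCTCCTGAACCACCCCGCCAACGGGAGGGTGTGCGAGAGAC
>IGHV3-30*01
CTCGGTGAAAGAAAGGCAGACGGCCTCGTCAAACGTGTACGCTGGGATGTAAGCATTCATTCAACTCGTTCTACCGCGGGATGCCCCGTCGCCCCGCGGGGAGGCGCCCGCGCCTCCCGGCTAAGGGAGTTGGACAGGCTATAAGGTAGAACGGACGCTCCCGCACGAAAGCCGGGTTCATCAGTCGCGCGCAACCCCTCGATGTGCTGGATCGTGCGGCGCGCGGCAGTGTTAACATCTCGTTCACGGGCCCGCATCTGTCAAGCGCCCCACCGAGGTCGCTGTGCGAGGGAT
>IGHV4-34*01
GACCCGTGAGCGGACGCGGAGGCACGAGATTTAACGGAGGACGTGTAACTCGCCTATATGTACCTCGATTACAAGATTTGCTTCTCTGCGCTTGCGTGGTGTTGCACCGCTACTAAGTCCGGCATCCCCCCCGCTCCCTGACATCGCGTGTTCGCAGGGAGGGAAATAGCTGTTTAGTTAGCGCCACCCTGTCTCCCGTGAACTGGTCCTCGGGCTGTGCGTTGCGCACAGCCGGGGGGCTTCTTAGCTATTCTTTCTCTCGGGATCCAACAAAGGGCCGGTGGGAGGTGTGCGAGAGTT
>IGHV4-39*01
AGCGTGTGGCGGCGGCTCGACAGGACGTCCGATTGCGCATGCTTTATCATTGAGATCATTAGGCGCTGCAAGCTGGGCCTCTTGGAGGTAAGGGCGGGCTTCGGTCACTCGCCTCCAATGCTATCCGACAATGGACAGGAGGCTTGCTTGCGCAATGTGGATGCGGGCGTGACGGTTCCACATTAGGCTCGCAGCAGCGGTGTCGAGATTGCGTTCACTTATCGTCCTGCGTAAGCCTAAAGGTATCTTTGTGCATCGGGGATCATTGTGATCATGGCACCGAGATGTGCAAGAGAT
>IGHV4-59*01
ACTGCCCAGACACTCGAGGGTCGCTCTCCTCTCAGACTACGGGAAGAGCCTCAATACACACACCGTAGGTCCCCCAGTGTGTCGCCACTTCAGAAGTTATCTCGCACAGTAATTGACTGGGGTCCCGGACACTGCCCTGTCGCGCATCCACATAGTCGCGAGGTAGACGCGGTAATGGCAAGGGACATATAGATTTCAGAGCAGCATTGATCTCTAAACGTGCGGGAATCGCACCCTACCCCGCAGTGCCCCGCGCTGCCAGCCCCAGTGGCGCGCGGTGTGTGTGCGAGAGCT
>IGHV5-51*01
CGGCGCCGTATATCGCATACGGTAGACGTATGGAGGGGAGATTCTCGAGCGCTGGCCCCAAGCTGAGTGTAAGGGAGCGACTGCACTGTCCCACTTCCATGACGAGCAGCGCCGCAGTGGGCCAACGTCGGGGGCGCGCGGATACTAGAACAGTACGGCACTAACGTGGTGCATCCGGCCGAGTCTGTTACGGCCATGCCGGCCCATTGGACATACGGGATCCACGATTTTTCATGACGTTAGACGATCCCCACAGCATTGCAGATTGAACAAGCTGGTTGTGCGACAGAT
>IGHV6-1*01
GTTCGTGCCGTGCATTTACACGCTACGGGATTAGGCCGAAAAGACTACGACAAGGTGGCGACTCCAACCGTCCCCCCCTGGTATGATGCTGAGTGCCCGCACGCGTCCGCCGAGGAGCGATTTAGGATCGCCGGGCGCCCACCGCAAACCGAGCGCCCTAGACGAGTCTGCGGGTTTCAACTTCAGATCCTCAGCGGTGGCGGGGTGACGGTCCGTGTATACTCCCATATCAGCTCGACCTAGCACTGAGCGACTGAAGCCTCTATAGGTAGCCTGCCCGTACGATGATGTGCAAGAGGT
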