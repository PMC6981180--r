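>IGHD1-1*01
AACTAACGGACCCTTAG
>IGHD1-26*01
AGCTCAGCCAATCGTACCGT
>IGHD2-2*01
TTTAGACAACACGAGCGCAGGCGCCGGAGCA
>IGHD2-15*01
CAGCGCGGTAAGTATCACCCATCGCACGAAC
>IGHD3-3*01
CCCGGCGCCCACAGCGGCGGCTCAATCGGCA
>IGHD3-10*01
TGTATCGCAAGGTGGGGTTGACGGCTCGAGA
>IGHD3-22*01
GGAGATAGTCCAGAGGCAGATGAAAAAA
>IGHD4-17*01
AGACTGCATAAGTTGT
>IGHD4-23*01
CGTCTGGAGCTGCCTGGGG
>IGHD5-12*01
GGGTCATTACGCGCGTACCGCAT
>IGHD6-19*01
CCAAGTCGTGGTGAAATGATA
>IGHD7-27*01
GTGTCCGACAA
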