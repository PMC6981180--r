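>IGHD1-1*01
GGTAACACCGCC
>IGHD1-26*01
GCCACGCCTTACC
>IGHD2-2*01
AATACTTGTTGGCCCGG
>IGHD2-15*01
TAGCCACCAAGCCCGC
>IGHD3-3*01
GGTGGTAAAGTCGCCCCA
>IGHD3-10*01
CTCATACGCCTACGAAG
>IGHD3-22*01
GTCCTTCTTTGGAATC
>IGHD4-17*01
AGATAGCCTC
>IGHD4-23*01
GACGGAACGCCA
>IGHD5-12*01
AGTCGAATTTGCCA
>IGHD6-19*01
TCGGGTTTAATAA
>IGHD7-27*01
GCGGGTGA
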