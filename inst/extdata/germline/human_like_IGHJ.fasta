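>IGHJ1*01
CACGACTGGTGGGGCCAAGGGACCACGGTCACCGTCTCCTCAG
>IGHJ2*01
GAACGAAAATGGGGCCAAGGGACCACGGTCACCGTCTCCTCAG
>IGHJ3*01
GAGACATTCTGGGGCCAAGGGACCACGGTCACCGTCTCCTCAG
>IGHJ4*01
CAGTCGGGTTGGGGCCAAGGGACCACGGTCACCGTCTCCTCAG
>IGHJ5*01
CTTAAACGGCTCTGGGGCCAAGGGACCACGGTCACCGTCTCCTCAG
>IGHJ6*01
ATCAGTGCATCCAACTGGGGCCAAGGGACCACGGTCACCGTCTCCTCAG
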