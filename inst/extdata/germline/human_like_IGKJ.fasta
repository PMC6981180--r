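>IGKJ1*01
GATGGCAAGCGGTTCGGCCAAGGGACCAAGGTGGAAATCAAAC
>IGKJ2*01
CACGCAGACGCTTTCGGCCAAGGGACCAAGGTGGAAATCAAAC
>IGKJ3*01
TAGGGGGGCATGTTCGGCCAAGGGACCAAGGTGGAAATCAAAC
>IGKJ4*01
CCCGGTTCGTCGTTCGGCCAAGGGACCAAGGTGGAAATCAAAC
>IGKJ5*01
CGTCACCCAAGTTTCGGCCAAGGGACCAAGGTGGAAATCAAAC
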