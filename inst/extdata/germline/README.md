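# Synthetic toy germline sets

All FASTA files here are synthetic, generated deterministically by
`vdjrep::toy_germline_set()` (see `?toy_germline_set`). Gene names follow
real IMGT-style nomenclature so family parsing behaves as on real data, but
the sequences are constructed. The `rat_like_IGHD.fasta` set has shorter D
genes than `human_like_IGHD.fasta` and exists for germline segment-length
comparisons only.
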