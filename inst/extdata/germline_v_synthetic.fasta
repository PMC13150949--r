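>VH14-1
GAGGTGCAGCTGGTGGAGTCTGGAGGAGGCTTGGTACAGCCTGGGACTTCTGTACAACT
>VH14-4
GAGGTGCAGCTGGTGGAGTCTGGAGGAGGCTTGGTACAGCCTGGGACTTCTGTACTACT
>VH1-9
CAGGTCCAGCTGCAGCAGTCTGGACCTGAGCTGGTGAAGCCTGGGGCTTCTGTGCAAGA
>VH5-17
GAAGTGAAGCTGGTGGAGTCTGGAGGAGGCTTGGTGCAGCCTGGAGGATCTGTGCAAGG
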