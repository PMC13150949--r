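>JH2
TACTTTGACTACTGG
>JH3
TGGTTTGCTTACTGG
>JH4
TACTATGCTATGGACTACTGG
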