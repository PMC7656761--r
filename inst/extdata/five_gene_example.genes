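# five-gene worked example: two unichromosomal genomes at DCJ distance 3
>G1
1 2 3 4 5 $
>G2
3 -2 -1 -4 5 $
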