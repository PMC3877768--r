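>miR21 role=mature
TAGCTTATCAGACTGATGTTGA
>miR21star role=star
CAACACCAGTCGATGGGCTGT
>miR30 role=mature
TGTAAACATCCTCGACTGGAAG
>miR20 role=mature
TAAAGTGCTTATAGTGCAGGTAG
>miR28 role=mature
AAGGAGCTCACAGTCTATTGAG
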