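>pri-let-7a-1 hsa-let-7a-1 hairpin in synthetic flanking context
CAAAAAAACAACAACACAAAAACAAAACCAUGGGAUGAGGUAGUAGGUUGUAUAGUUUUA
GGGUCACACCCACCACUGGGAGAUAACUAUACAAUCUACUGUCUUUCCUACAAACCAAAA
ACACAACCCCCCCCCCACCA
>pri-miR-26b hsa-mir-26b hairpin in synthetic flanking context
CCAACAACCCAACAAAAAAAAAAAACACACCCGGGACCCAGUUCAAGUAAUUCAGGAUAG
GUUGUGUGCUGUCCAGCCUGUUCUCCAUUACUUGGCUCGGGGACCGGCCACAAACAACCC
ACCCACAACAAACCCCA
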