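>TRBV1 anchor=55
GATCGCGATCCATACGACAATACGTATAGTTTATCGAGACCCATCCCAAAGCCGCTGTCCAGATTTCCCA
>TRBV2 anchor=55
GATCGCGGTCTGTATGACAAAACGTTTAGTTCGGCAAGAACATTCAAAAATCTGCTGTCCTTTGTACGCC
>TRBV3 anchor=55
GATCGCGACCCATATTACAGAACGTATAGTACATCGAGAACAATCACAAAGCCGCTGTCCGGTTTTCCCC
>TRBV4 anchor=55
GCTCGCCATCCATACGACAAAACGTAAAGTTCATCGACAACAATCACAAGGCCACTGTACAGTTTCCCCC
>TRBV5 anchor=55
GATCGCGATCCATACGAGAAAAGTTATAGATCGTCCAGAGCAATAACAAAGCCGCTGTCCAGTTTTATCC
>TRBV6 anchor=55
GACCTCGATCTATACGAAAATACGCTTGGTTCATTGAGAACAAGGATGAAGCCGCTGTCGAGTTTTCCCC
>TRBV7 anchor=55
CATCGCGATCCATCCGAAAAAACGTATAGTTTATCGAGAACAATCACAAGGCCGCTGTCCAGTTTTCCCC
>TRBV8 anchor=55
GCTCGCGACCCCTCCGACAAACCGTATAGTTCATCGATAACAACCACAAAGCCGCTGTCCTGTTCTTCCC
>TRBD1
AACGTTGATTCCACAC
>TRBD2
ACGCGGACTGTACA
>TRBJ1-1 family=J1 anchor=13
AGACGTACTAGTCTTTCCTT
>TRBJ1-2 family=J1 anchor=13
AGACGAAATAGTCTTTCCTT
>TRBJ1-3 family=J1 anchor=13
AAACGAAATCGTCTTTCCTT
>TRBJ2-1 family=J2 anchor=13
CTCAAGAGTTCTATGGCATG
>TRBJ2-2 family=J2 anchor=13
ATCAAGAGTTCTATGGTGCG
>TRBJ2-3 family=J2 anchor=13
ATCAAGAGTCCTATGGCGCG
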