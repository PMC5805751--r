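>IGHV1 anchor=105
GGTTTCGCAGGGTTGTTTTATAATGAGGCCTCGTGTAAGAATATATCTGCCGCGTTACGATCCTGTACCACGACGAGAGTGAGAACAGAGGTCTGAGGTATAACGTGTATAATTCGTTGG
>IGHV2 anchor=105
AGGAACATAGGCTAGTTTTTTTATAACAGCTCTAATAAGTATATATCTGCCGCGGTAGGAGCCTGGGCTAGGACGAGAGAGAGAACGGATGTCGTACGTACATCGTGTCTTTTTATTTGG
>IGHV3 anchor=105
AGGAACATAGGCTTAACTTATAAGGACGGCTCGTGTTGGTTTATATCTGAGGCTTTACGATCTTGTGCTAGGCCGAGGGAAAGAACAGAGGTCGTAGGTGCTACCTGTCTTATCCTTTGG
>IGHV4 anchor=105
GGGCACACAGGCGTGATATATACTGACGGCTCGTGAAGGTTTATATCGGCCGCGTTAAGCTCCTTTCCTACTACGCGAGATTGACCCGAGGTCGTAGGTGCAACGTGTCTAATGGATCGC
>IGHV5 anchor=105
GGTAACATAGCGTGCCTTTATAATTACGGCTCGTGTAAGTTTCTATCTGCCGCGTTACGATCCTGAGCTGGCACGAGAGAGACAACAGTCGTCTTAGTAGCAACGTGTTTTATCCTTTGG
>IGHV6 anchor=105
GGGAACAGTGTCCTTCTCTGTAATTACGTCTAGTGTAGGTCTATCGCTGCCGCGGTAGACTCGCGTGCTACGACGATAGAGTTAACAGAGTACGTAGGGGCAACGTGTCTTATTGTTTGG
>IGHV7 anchor=105
CCGAACATAAGCTTGTTTTATTACCACGGCTTGTGTAGGTTTCTACCTGCCGCGTTAGGATCCTGTCCTAGAACGAGAAAGTGACCAGAGGTCGTAAGTGCGAAGTGTCTTAATCTGGGG
>IGHV8 anchor=105
GGCAACATAGGCTAGTTTAATAATGACGGATAGTGGAGGGTTTTATCTGCGGCGTTAGGATCCTGTGTTAGGAAATGAGAGAGAATAGATGTCGTTGGTGCCACGTGTATCATACAATAG
>IGHV9 anchor=105
GGAATTACCGGCTTGTTTTCTAATCACGGCTACAGTCTGTTTCTACATGCCGCGGTAGGATCCTGTAGTACGACGAGAGAGAGGACAGAGGTGGTTGGAGCAACGTGTGATACTCTTTCG
>IGHV10 anchor=105
GGGACCGTAGGCTTGTTCCACAATTACTGCTCATGCATGTTTATAACTACCGCTGTAGCATACAGTGCTTGGACGAGAGAGACAACAGAGGTCCTAGCTGCGATGTGTGTTATACTATGA
>IGHD1
CATCACAGCCTT
>IGHD2
TCCATCTCATCCTGCA
>IGHD3
AGACCATCACATCGAGCTAGT
>IGHD4
ATCCGGCGCTGCCACCACCAAGGA
>IGHD5
GACAATCCGGGCTGTCACGACCAAGTCGTCG
>IGHJ1 family=JH anchor=30
GCCGCTTGTCATTATCTCTAAATCAATTCGTGGTCAGCCG
>IGHJ2 family=JH anchor=30
ACCGCCTGACATTATCTGTAAATTAATTCGTGGTCAGACG
>IGHJ3 family=JH anchor=30
ACCGTCGGTCATAATCTGGAAGTTAAATCGTGGTCAGCCC
>IGHJ4 family=JH anchor=30
ACCCCCCGTCATAATCTGTTAATTCATTCCTGGTCAGCCG
>IGHJ5 family=JH anchor=30
ACCGCACGTTATTATCTCTAAAAGAATTCTTGGTCAGCCG
>IGHJ6 family=JH anchor=30
ACCGCCCTTCATTATCTCTAAATTAGCTCGTGGTCAGCCG
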