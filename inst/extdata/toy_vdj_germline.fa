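>TV1
CTGCCGTCCATTTCTACAAT
>TV2
AGGACTGGGGTAGCCAGTTT
>TV3
TTCTAGGTAAAGACAAGGTC
>TD1
AATGAG
>TD2
CTCGTA
>TJ1 family=J1
CCTCTGCCAGAC
>TJ2 family=J1
AGGTCGAGATGG
>TJ3 family=J2
TCGGCACCTTTG
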