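>TV1
GGGTCGCGCTTCATTATTAC
>TV2
GTGGTTACTTATATATTGGG
>TJ1
AGCAGAAACCTC
>TJ2
ATACATCTACTA
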