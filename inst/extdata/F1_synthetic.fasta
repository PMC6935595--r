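>s1
ACGTACGTACGTACGTACGTACGTACGTACGTCCGTACGT
>s2
ACTTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>s3
ACGTACGTANGTACGTACGTACGTACGTACGTACGTACGT
>s4
ACGTACGTAGGTACGTACGTACGTACGTACGTACGTACGT
>s5
ACGTACGTAGGTACGTGCGTACGTACGTACGTACGTACGT
>s6
ACGTACGTAGGTACGTGCGTACGTTCGTACGTACGTACGT
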