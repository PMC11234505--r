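>s1
ACGT
>s2
ACGA
>s3
ATGA
>s4
ATGA
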