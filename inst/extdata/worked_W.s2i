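# sequence	individual	population
s1	ind1	P1
s2	ind2	P1
s3	ind3	P2
s4	ind4	P2
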