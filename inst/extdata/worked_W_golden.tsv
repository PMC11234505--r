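# Hand-enumerated statistics for the worked alignment W
# (s1=ACGT s2=ACGA s3=ATGA s4=ATGA; P1={s1,s2}, P2={s3,s4}).
# Pairwise differences: s1s2=1 s1s3=2 s1s4=2 s2s3=1 s2s4=1 s3s4=0; sum=7 over 6 pairs.
# pi_locus = 7/6; a1 = 1+1/2+1/3 = 11/6; theta_W = 2/(11/6) = 12/11.
# Tajima 1989 coefficients at n=4: a1=11/6 a2=49/36 b1=5/9 b2=23/54
#   c1=1/99 c2=0.01270343 e1=0.005509642 e2=0.002690002
#   D = (7/6 - 12/11)/sqrt(2*e1 + 2*e2) = 0.59158
# ZnS: sites 2 and 4; haplotypes CT,CA,TA,TA; pA=1/2 pB=1/4 pAB=1/4
#   D'=1/8, r2 = (1/64)/(1/4*3/4*1/4... ) = 1/3.
# Subdivision: Hw=(1+0)/2=0.5 Hb=(2+2+1+1)/4=1.5 Fst=1-0.5/1.5=2/3
#   Ks=(2*1+2*0)/4=0.5 Kt=7/6 Kst=1-0.5/(7/6)=4/7
#   site 2 fixed (CC vs TT), site 4 private to P1.
statistic	value
S	2
pi_locus	1.1666666667
theta_w_locus	1.0909090909
tajimas_D	0.5915801399
znS	0.3333333333
Fst	0.6666666667
Kst	0.5714285714
n_fixed	1
n_shared	0
n_private_1	1
n_private_2	0
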