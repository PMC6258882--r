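participant,cov_percent
1,0.03
2,1.01
3,1.03
4,1.04
5,1.98
6,2.51
7,2.53
8,3.46
9,6.11
10,8.00
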