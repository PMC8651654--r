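pair,from,to,fraction
s1_vs_s2,rare,rare,0.4
s1_vs_s2,intermediate,rare,0.4444444444
s1_vs_s2,high,rare,0
s1_vs_s2,rare,intermediate,0.6
s1_vs_s2,intermediate,intermediate,0.4444444444
s1_vs_s2,high,intermediate,0.1666666667
s1_vs_s2,rare,high,0
s1_vs_s2,intermediate,high,0.1111111111
s1_vs_s2,high,high,0.8333333333
s1_vs_s3,rare,rare,0.2
s1_vs_s3,intermediate,rare,0.2222222222
s1_vs_s3,high,rare,0
s1_vs_s3,rare,intermediate,0.8
s1_vs_s3,intermediate,intermediate,0.6666666667
s1_vs_s3,high,intermediate,0.1666666667
s1_vs_s3,rare,high,0
s1_vs_s3,intermediate,high,0.1111111111
s1_vs_s3,high,high,0.8333333333
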