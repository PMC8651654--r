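session,mean_r,shuffled_mean_r,mean_r_whisk,mean_r_stationary,n_undefined
1,0.01258905738,-0.0006114977795,0.004990193377,0.01674791543,0
2,0.0009058416755,-0.002254906269,0.01965011643,-0.0002320122784,0
3,0.02117539042,0.00110831217,0.002726061436,0.02401784166,0
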