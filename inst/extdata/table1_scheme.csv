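# FEXI acquisition scheme: bbb-fexi full protocol
bf_s_per_mm2,tm_ms,b_s_per_mm2,TEf_ms,TE_ms,n_rep
0,20,0,38,62,15
0,20,50,38,62,15
0,20,100,38,62,15
0,20,250,38,62,15
0,20,1000,38,62,15
250,20,0,38,62,15
250,20,50,38,62,15
250,20,100,38,62,15
250,20,250,38,62,15
250,20,1000,38,62,15
250,200,0,38,62,15
250,200,50,38,62,15
250,200,100,38,62,15
250,200,250,38,62,15
250,200,1000,38,62,15
250,400,0,38,62,15
250,400,50,38,62,15
250,400,100,38,62,15
250,400,250,38,62,15
250,400,1000,38,62,15
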