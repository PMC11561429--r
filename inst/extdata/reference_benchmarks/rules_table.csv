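topic_id,n_positive,rate_pct,relevant_n,relevant_sample
1,1125,0.041,45,50
2,1706,0.062,45,50
3,2077,0.075,44,50
4,1102,0.040,44,50
5,1444,0.052,36,50
6,1331,0.048,44,50
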