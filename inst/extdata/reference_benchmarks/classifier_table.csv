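topic_id,high_score_negatives,relevant_n,roc_auc,pr_auc,prec_at_2n,prec_at_10n,rec_at_2n,rec_at_10n
1,309,255,99.33,22.77,20.00,5.87,40.00,58.67
2,299,234,94.87,24.55,19.64,5.79,39.29,57.86
3,272,270,99.92,42.75,36.56,9.78,73.12,97.85
4,151,150,99.98,84.62,48.75,10.00,97.50,100.00
5,220,161,99.86,39.65,29.85,8.06,59.70,80.60
6,230,227,99.93,68.72,42.13,9.81,84.26,98.15
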