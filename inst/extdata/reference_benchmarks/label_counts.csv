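quantity,value
train_positives,6512
train_negatives,100000
val_positives,723
val_total,270324
relevancy_confirmed,258
relevancy_sample,300
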