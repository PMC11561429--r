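supervision,topic_1,topic_2,topic_3,topic_4,topic_5,topic_6
none,21.90,19.76,27.65,25.37,25.35,25.34
selected,45.41,37.27,49.96,50.77,47.20,37.79
human,47.61,38.22,48.67,49.58,48.71,37.96
selected_human,52.15,38.49,47.19,47.78,51.85,42.00
cnndm,45.33,36.80,45.86,48.57,48.19,35.81
cnndm_selected,44.71,28.69,44.65,40.08,44.82,35.55
cnndm_human,53.97,43.91,49.75,49.08,55.61,43.08
final,53.76,40.74,49.08,47.55,52.45,42.99
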