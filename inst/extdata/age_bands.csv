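age_band,fraction
0-14,0.226
15-64,0.683
65+,0.091
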