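endpoint,zone,rate_per_100k
respiratory mortality,coastal,36.92
respiratory mortality,industrial,20.26
respiratory mortality,mountainous,18.29
cardiovascular mortality,coastal,77.47
cardiovascular mortality,industrial,16.82
cardiovascular mortality,mountainous,27.1
lung cancer mortality,coastal,4.67
lung cancer mortality,industrial,4.91
lung cancer mortality,mountainous,2.19
respiratory hospital admissions,coastal,768
respiratory hospital admissions,industrial,1421
respiratory hospital admissions,mountainous,1007
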